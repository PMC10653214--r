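#' Parse a SMILES string into an explicit molecular graph
#'
#' A deliberately small, dependency-free SMILES reader covering the organic
#' subset this package's synthetic grammar and test fixtures use: elements
#' B/C/N/O/F/P/S/Cl/Br/I, aromatic `c/n/o/s`, single/double/triple bonds,
#' branches, numeric ring closures, and simple bracket atoms. It exists as the
#' *independent route* for structural checks (perfluoroalkyl chain walking,
#' ester detection, subgraph matching, fingerprint environment enumeration):
#' the production filters go through RDKit SMARTS, and the two routes are
#' compared in the test suite. It is not a general-purpose SMILES parser.
#'
#' @param smiles a single SMILES string.
#' @return a list with `atoms` (data.frame: `symbol`, `aromatic`) and `bonds`
#'   (data.frame: `a1`, `a2`, `order`; aromatic bonds have order 1.5).
#' @export
smiles_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "")[[1L]]
  sym <- character(0); arom <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bord <- numeric(0)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_real_      # explicit bond order awaiting the next atom
  ring <- list()           # digit -> c(atom, pending order)
  two_letter <- c("Cl", "Br")
  i <- 1L
  n <- length(chars)

  add_atom <- function(symbol, aromatic) {
    sym[length(sym) + 1L] <<- symbol
    arom[length(arom) + 1L] <<- aromatic
    idx <- length(sym)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) pending
             else if (aromatic && arom[prev]) 1.5 else 1
      b1[length(b1) + 1L] <<- prev; b2[length(b2) + 1L] <<- idx
      bord[length(bord) + 1L] <<- ord
    }
    pending <<- NA_real_
    prev <<- idx
  }

  while (i <= n) {
    ch <- chars[i]
    nxt <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (nxt %in% two_letter) {
      add_atom(nxt, FALSE); i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "F", "P", "S", "I")) {
      add_atom(ch, FALSE); i <- i + 1L; next
    }
    if (ch %in% c("c", "n", "o", "s")) {
      add_atom(toupper(ch), TRUE); i <- i + 1L; next
    }
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      el <- regmatches(body, regexpr("[A-Za-z][a-z]?", body))
      if (length(el) != 1L) stop("unsupported bracket atom: [", body, "]")
      aromatic <- el %in% c("c", "n", "o", "s")
      add_atom(if (aromatic) toupper(el) else el, aromatic)
      i <- j + 1L; next
    }
    if (ch == "=") { pending <- 2; i <- i + 1L; next }
    if (ch == "#") { pending <- 3; i <- i + 1L; next }
    if (ch == "-") { pending <- 1; i <- i + 1L; next }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("[1-9]", ch)) {
      key <- ch
      if (is.null(ring[[key]])) {
        ring[[key]] <- c(prev, if (is.na(pending)) -1 else pending)
        pending <- NA_real_
      } else {
        open <- ring[[key]]; ring[[key]] <- NULL
        ord <- if (!is.na(pending)) pending
               else if (open[2L] >= 0) open[2L]
               else if (arom[open[1L]] && arom[prev]) 1.5 else 1
        b1[length(b1) + 1L] <- open[1L]; b2[length(b2) + 1L] <- prev
        bord[length(bord) + 1L] <- ord
        pending <- NA_real_
      }
      i <- i + 1L; next
    }
    if (ch %in% c("/", "\\")) { i <- i + 1L; next }  # stereo bonds read as single
    stop("unsupported SMILES character '", ch, "' in: ", smiles)
  }
  if (length(ring) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  list(
    atoms = data.frame(symbol = sym, aromatic = arom, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord)
  )
}

# adjacency: list per atom of data.frame(nb, order)
graph_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- rep(list(integer(0)), n)
  ords <- rep(list(numeric(0)), n)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds$a1[r]; j <- g$bonds$a2[r]; o <- g$bonds$order[r]
      adj[[i]] <- c(adj[[i]], j); ords[[i]] <- c(ords[[i]], o)
      adj[[j]] <- c(adj[[j]], i); ords[[j]] <- c(ords[[j]], o)
    }
  }
  list(nb = adj, order = ords)
}

#' Chain-walk test for a perfluoroalkyl run of three carbons
#'
#' Independent graph-search route for the C3F6 membership rule: does the
#' molecule contain a bonded path of three distinct saturated (all-single-bond)
#' carbons carrying at least 2, 2 and 1 fluorine substituents respectively?
#' This mirrors the semantics of the production SMARTS
#' `[CX4]([F])([F])[CX4]([F])([F])[CX4][F]` without going through RDKit.
#'
#' @param smiles a single SMILES string (parsed by [smiles_graph()]).
#' @return logical scalar.
#' @export
has_perfluoro_c3 <- function(smiles) {
  g <- smiles_graph(smiles)
  a <- graph_adjacency(g)
  n <- nrow(g$atoms)
  is_sat_c <- vapply(seq_len(n), function(i) {
    g$atoms$symbol[i] == "C" && !g$atoms$aromatic[i] &&
      (length(a$order[[i]]) == 0L || all(a$order[[i]] == 1))
  }, logical(1))
  n_f <- vapply(seq_len(n), function(i) {
    sum(g$atoms$symbol[a$nb[[i]]] == "F")
  }, integer(1))
  cand2 <- which(is_sat_c & n_f >= 2L)   # ends with >=2 F
  if (length(cand2) < 2L) return(FALSE)
  for (c2 in cand2) {
    nbs <- a$nb[[c2]]
    c1s <- intersect(nbs, cand2)
    c3s <- nbs[is_sat_c[nbs] & n_f[nbs] >= 1L]
    for (c1 in c1s) {
      if (any(c3s != c1)) return(TRUE)
    }
  }
  FALSE
}

#' Graph-walk detection of a carbon-fluorine bond
#' @param smiles a single SMILES string.
#' @return logical scalar.
#' @export
has_cf_bond <- function(smiles) {
  g <- smiles_graph(smiles)
  if (nrow(g$bonds) == 0L) return(FALSE)
  s <- g$atoms$symbol
  any((s[g$bonds$a1] == "C" & s[g$bonds$a2] == "F") |
      (s[g$bonds$a2] == "C" & s[g$bonds$a1] == "F"))
}

#' Graph-walk detection of a carboxylic-ester linkage
#'
#' Independent route for the ester SMARTS `[CX3](=O)[OX2][#6]`: a carbon
#' double-bonded to one oxygen and single-bonded to a second oxygen that in
#' turn bonds another carbon (so free acids, where that oxygen carries only
#' hydrogen, do not qualify).
#'
#' @param smiles a single SMILES string.
#' @return logical scalar.
#' @export
has_ester_linkage <- function(smiles) {
  g <- smiles_graph(smiles)
  a <- graph_adjacency(g)
  n <- nrow(g$atoms)
  for (c_idx in seq_len(n)) {
    if (g$atoms$symbol[c_idx] != "C" || g$atoms$aromatic[c_idx]) next
    nbs <- a$nb[[c_idx]]; ords <- a$order[[c_idx]]
    has_carbonyl <- any(g$atoms$symbol[nbs] == "O" & ords == 2)
    if (!has_carbonyl) next
    ethers <- nbs[g$atoms$symbol[nbs] == "O" & ords == 1]
    for (o_idx in ethers) {
      others <- setdiff(a$nb[[o_idx]], c_idx)
      if (any(g$atoms$symbol[others] == "C") &&
          all(a$order[[o_idx]] == 1)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Enumerate distinct circular atom environments up to a radius
#'
#' Oracle for the ECFP popcount check: counts the distinct hashed circular
#' environments a Morgan-style fingerprint would emit for small molecules.
#' Follows the Morgan bookkeeping rules: every atom contributes its radius-0
#' invariant; a larger-radius environment is only emitted when it covers new
#' bonds, and environments covering a bond set already emitted (by any atom at
#' any radius) are dropped; the count is the number of distinct canonical
#' environment identifiers among the survivors. Exact up to hash collisions,
#' which are negligible at 2048 bits for the molecule sizes this is used on.
#'
#' @param smiles a single SMILES string.
#' @param radius max environment radius (ECFP4 = radius 2).
#' @return integer count of distinct environments.
#' @export
count_morgan_environments <- function(smiles, radius = 2L) {
  g <- smiles_graph(smiles)
  a <- graph_adjacency(g)
  n <- nrow(g$atoms)
  deg <- vapply(a$nb, length, integer(1))
  # radius-0 invariant: element, aromaticity, heavy degree, summed bond order
  inv0 <- vapply(seq_len(n), function(i) {
    paste(g$atoms$symbol[i], g$atoms$aromatic[i], deg[i],
          sum(a$order[[i]]), sep = "|")
  }, character(1))

  bond_key <- function(i, j) paste(min(i, j), max(i, j))
  env_bonds <- function(center, r) {
    # all bonds within graph distance r of center
    seen <- center; frontier <- center; keys <- character(0)
    for (step in seq_len(r)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in a$nb[[v]]) {
          keys <- c(keys, bond_key(v, w))
          if (!(w %in% seen)) nxt <- c(nxt, w)
        }
      }
      seen <- c(seen, nxt); frontier <- unique(nxt)
      if (length(frontier) == 0L) break
    }
    sort(unique(keys))
  }
  env_id <- function(center, r) {
    # Weisfeiler-Lehman refinement restricted to the radius-r ball
    lab <- inv0
    for (step in seq_len(max(r, 1L)) - (r == 0L)) {
      if (r == 0L) break
      lab <- vapply(seq_len(n), function(i) {
        nb_lab <- sort(paste0(a$order[[i]], ":", lab[a$nb[[i]]]))
        paste(lab[i], paste(nb_lab, collapse = ","), sep = ";")
      }, character(1))
    }
    paste0("r", r, "{", lab[center], "}")
  }

  emitted_sets <- character(0)
  ids <- character(0)
  for (r in 0:radius) {
    for (atom in seq_len(n)) {
      bonds <- env_bonds(atom, r)
      if (r > 0L) {
        if (length(bonds) == 0L) next
        prev_bonds <- env_bonds(atom, r - 1L)
        if (length(bonds) == length(prev_bonds)) next  # no growth
        set_key <- paste(bonds, collapse = "+")
        if (set_key %in% emitted_sets) next
        emitted_sets <- c(emitted_sets, set_key)
      }
      ids <- c(ids, env_id(atom, r))
    }
  }
  length(unique(ids))
}

#' Subgraph containment of one parsed molecule in another
#'
#' A plain backtracking (VF2-style) subgraph-isomorphism check on the graphs
#' produced by [smiles_graph()], used as the independent oracle for RDKit
#' SMARTS matching of concrete fragments. `pattern` is itself given as SMILES
#' (a fragment with full valence, e.g. `"COC(C)=O"` is *not* a pattern here —
#' pass the fragment atoms you mean, e.g. `"CC(=O)OC"` matches ethyl acetate).
#' Element symbols must match exactly and bond orders must match, with
#' aromatic bonds (order 1.5) treated as compatible only with aromatic bonds.
#'
#' @param target_smiles molecule searched in.
#' @param pattern_smiles fragment searched for.
#' @return logical scalar.
#' @export
contains_subgraph <- function(target_smiles, pattern_smiles) {
  tg <- smiles_graph(target_smiles)
  pg <- smiles_graph(pattern_smiles)
  ta <- graph_adjacency(tg); pa <- graph_adjacency(pg)
  np <- nrow(pg$atoms); nt <- nrow(tg$atoms)
  if (np > nt) return(FALSE)
  # order pattern atoms so each (after the first) touches an earlier one
  ord <- 1L
  while (length(ord) < np) {
    nxt <- setdiff(unique(unlist(pa$nb[ord])), ord)
    if (length(nxt) == 0L) nxt <- setdiff(seq_len(np), ord)[1L]
    ord <- c(ord, nxt[1L])
  }
  compatible <- function(pi, ti) {
    pg$atoms$symbol[pi] == tg$atoms$symbol[ti] &&
      pg$atoms$aromatic[pi] == tg$atoms$aromatic[ti]
  }
  bond_ok <- function(po, to) (po == to) || (po == 1 && to == 1.5) ||
    (po == 1.5 && to == 1)
  assign_map <- integer(np)
  recurse <- function(k) {
    if (k > np) return(TRUE)
    pi <- ord[k]
    # candidate targets: neighbors of an already-mapped pattern neighbor
    mapped_nb <- intersect(pa$nb[[pi]], ord[seq_len(k - 1L)])
    cands <- if (length(mapped_nb) > 0L) {
      ta$nb[[assign_map[mapped_nb[1L]]]]
    } else seq_len(nt)
    for (ti in cands) {
      if (ti %in% assign_map[ord[seq_len(k - 1L)]]) next
      if (!compatible(pi, ti)) next
      ok <- TRUE
      for (pn in mapped_nb) {
        tn <- assign_map[pn]
        e_p <- pa$order[[pi]][match(pn, pa$nb[[pi]])]
        pos <- match(tn, ta$nb[[ti]])
        if (is.na(pos) || !bond_ok(e_p, ta$order[[ti]][pos])) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_map[pi] <<- ti
      if (recurse(k + 1L)) return(TRUE)
      assign_map[pi] <<- 0L
    }
    FALSE
  }
  recurse(1L)
}
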