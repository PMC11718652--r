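# Molecular graphs from SMILES -------------------------------------------
#
# Supported dialect: organic-subset atoms B C N O P S F Cl Br I, aromatic
# b c n o p s, bracket atoms with isotope/charge/explicit H, branches,
# ring closures (digits and %nn), bond symbols - = # : / \, and dot
# disconnection. Stereo markers and isotopes are accepted and ignored:
# both fingerprint types here are stereo-agnostic.

.ATOMIC_NUMBER <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L
)

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1, H = 1)

# valences reachable by promotion (hypervalent P and S)
.ALLOWED_VALENCES <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1, H = 1,
  P = c(3, 5), S = c(2, 4, 6)
)

.ORGANIC_TOKENS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_TOKENS <- c("b", "c", "n", "o", "p", "s")

smiles_error <- function(type, msg, pos, smiles) {
  full <- sprintf("SMILES parse error (%s) at position %d in \"%s\": %s",
                  type, pos, smiles, msg)
  stop(structure(
    list(message = full, call = NULL),
    class = c(paste0("smiles_", type, "_error"), "smiles_parse_error",
              "error", "condition")
  ))
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds an explicit heavy-atom graph from a SMILES string: atoms with
#' element, formal charge, aromatic flag and derived implicit hydrogen
#' count; bonds with order codes (1 single, 2 double, 3 triple,
#' 4 aromatic); ring membership flags from cycle detection. Atom indices
#' follow SMILES token order and are 0-based. Stereochemistry and isotopes
#' are accepted but ignored; aromaticity is taken from the input (lowercase
#' atoms / `:` bonds), not re-perceived.
#'
#' Implicit hydrogens follow default valences (B 3, C 4, N 3, O 2, P 3,
#' S 2, halogens 1; P and S may promote when the bond-order sum demands
#' it). For aromatic atoms each aromatic bond counts one unit plus one
#' unit for the delocalized system, except where that extra unit alone
#' would exceed the element's maximum valence (lone-pair donors such as
#' furan oxygen). Bracket atoms carry exactly the hydrogens they declare.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `molecular_graph`: a list with `atoms`
#'   (data.frame: `index`, `element`, `atomic_number`, `formal_charge`,
#'   `aromatic`, `explicit_h` (-1 when unspecified), `implicit_h`,
#'   `in_ring`), `bonds` (data.frame: `atom_a`, `atom_b`, `order_code`,
#'   `in_ring`), `rings` (list of 0-based atom index cycles),
#'   `aromatic_rings` (indices into `rings`), and `source_smiles`.
#' @examples
#' g <- parse_smiles("CCO")
#' g$atoms$implicit_h   # 3 2 1
#' parse_smiles("c1ccccc1")$atoms$aromatic
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }

  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n_char <- length(chars)

  atoms <- list()      # each: list(element, aromatic, charge, explicit_h, bracket)
  bonds <- list()      # each: c(a, b, order)  (1-based atom ids during parse)
  token_end <- integer()  # position in string where each atom unit ends

  prev_atom <- NA_integer_
  pending_bond <- NA_integer_
  branch_stack <- integer()
  ring_open <- list()  # label -> list(atom, order, pos)

  add_atom <- function(element, aromatic, charge = 0L, explicit_h = -1L,
                       bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = as.integer(charge),
      explicit_h = as.integer(explicit_h), bracket = bracket
    )
    token_end[length(atoms)] <<- i - 1L  # caller sets i past the token
    length(atoms)
  }

  add_bond <- function(a, b, order, pos) {
    if (a == b) {
      smiles_error("ring_closure", "ring bond joins an atom to itself",
                   pos, smiles)
    }
    for (bd in bonds) {
      if ((bd[1] == a && bd[2] == b) || (bd[1] == b && bd[2] == a)) {
        smiles_error("ring_closure", "duplicate bond between the same atoms",
                     pos, smiles)
      }
    }
    bonds[[length(bonds) + 1L]] <<- c(a, b, order)
  }

  bond_order_between <- function(a, b, explicit_order) {
    if (!is.na(explicit_order)) return(explicit_order)
    if (atoms[[a]]$aromatic && atoms[[b]]$aromatic) 4L else 1L
  }

  close_ring <- function(label, pos) {
    key <- as.character(label)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      order <- pending_bond
      if (is.na(order)) order <- op$order
      if (!is.na(op$order) && !is.na(pending_bond) &&
          op$order != pending_bond) {
        smiles_error("ring_closure",
                     sprintf("conflicting bond orders on ring closure %s",
                             key), pos, smiles)
      }
      add_bond(op$atom, prev_atom,
               bond_order_between(op$atom, prev_atom, order), pos)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = prev_atom, order = pending_bond,
                                pos = pos)
    }
    pending_bond <<- NA_integer_
  }

  i <- 1L
  while (i <= n_char) {
    ch <- chars[i]
    two <- if (i < n_char) paste0(ch, chars[i + 1L]) else ""

    if (ch == "(") {
      if (is.na(prev_atom)) {
        smiles_error("parenthesis", "branch opened before any atom", i, smiles)
      }
      branch_stack <- c(branch_stack, prev_atom)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L) {
        smiles_error("parenthesis", "unmatched closing parenthesis", i, smiles)
      }
      prev_atom <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev_atom <- NA_integer_
      pending_bond <- NA_integer_
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L,
                             "/" = 1L, "\\" = 1L)
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (is.na(prev_atom)) {
        smiles_error("ring_closure", "ring closure before any atom", i, smiles)
      }
      if (ch == "%") {
        if (i + 2L > n_char || !grepl("^[0-9][0-9]$",
                                      paste0(chars[i + 1L], chars[i + 2L]))) {
          smiles_error("ring_closure", "'%' must be followed by two digits",
                       i, smiles)
        }
        label <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
        i <- i + 3L
      } else {
        label <- as.integer(ch)
        i <- i + 1L
      }
      close_ring(label, i - 1L)
      token_end[prev_atom] <- i - 1L
    } else if (ch == "[") {
      res <- parse_bracket_atom(chars, i, smiles)
      i <- res$next_i
      idx <- add_atom(res$element, res$aromatic, res$charge, res$explicit_h,
                      bracket = TRUE)
      if (!is.na(prev_atom)) {
        add_bond(prev_atom, idx,
                 bond_order_between(prev_atom, idx, pending_bond), i - 1L)
      }
      prev_atom <- idx
      pending_bond <- NA_integer_
    } else if (two %in% .ORGANIC_TOKENS) {
      i <- i + 2L
      idx <- add_atom(two, FALSE)
      if (!is.na(prev_atom)) {
        add_bond(prev_atom, idx,
                 bond_order_between(prev_atom, idx, pending_bond), i - 1L)
      }
      prev_atom <- idx
      pending_bond <- NA_integer_
    } else if (ch %in% .ORGANIC_TOKENS) {
      i <- i + 1L
      idx <- add_atom(ch, FALSE)
      if (!is.na(prev_atom)) {
        add_bond(prev_atom, idx,
                 bond_order_between(prev_atom, idx, pending_bond), i - 1L)
      }
      prev_atom <- idx
      pending_bond <- NA_integer_
    } else if (ch %in% .AROMATIC_TOKENS) {
      i <- i + 1L
      idx <- add_atom(toupper(ch), TRUE)
      if (!is.na(prev_atom)) {
        add_bond(prev_atom, idx,
                 bond_order_between(prev_atom, idx, pending_bond), i - 1L)
      }
      prev_atom <- idx
      pending_bond <- NA_integer_
    } else {
      smiles_error("element", sprintf("unknown token '%s'", ch), i, smiles)
    }
  }

  if (length(branch_stack) > 0L) {
    smiles_error("parenthesis", "unbalanced parentheses: branch never closed",
                 n_char, smiles)
  }
  open_labels <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_labels) > 0L) {
    smiles_error("ring_closure",
                 sprintf("unmatched ring closure label(s): %s",
                         paste(open_labels, collapse = ", ")),
                 n_char, smiles)
  }
  if (length(atoms) == 0L) {
    smiles_error("element", "no atoms found", 1L, smiles)
  }

  n <- length(atoms)
  bond_df <- if (length(bonds) > 0L) {
    m <- do.call(rbind, bonds)
    data.frame(atom_a = m[, 1] - 1L, atom_b = m[, 2] - 1L,
               order_code = as.integer(m[, 3]), in_ring = FALSE)
  } else {
    data.frame(atom_a = integer(), atom_b = integer(),
               order_code = integer(), in_ring = logical())
  }

  atom_df <- data.frame(
    index = seq_len(n) - 1L,
    element = vapply(atoms, `[[`, character(1), "element"),
    atomic_number = .ATOMIC_NUMBER[vapply(atoms, `[[`, character(1),
                                          "element")],
    formal_charge = vapply(atoms, `[[`, integer(1), "charge"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    explicit_h = vapply(atoms, `[[`, integer(1), "explicit_h"),
    bracket = vapply(atoms, `[[`, logical(1), "bracket"),
    token_end = token_end,
    row.names = NULL
  )

  rings <- find_rings(n, bond_df)
  ring_atoms <- unique(unlist(rings))
  atom_df$in_ring <- atom_df$index %in% ring_atoms
  if (nrow(bond_df) > 0L) {
    bond_df$in_ring <- vapply(seq_len(nrow(bond_df)), function(k) {
      bond_in_some_ring(bond_df$atom_a[k], bond_df$atom_b[k], rings)
    }, logical(1))
  }

  aromatic_rings <- which(vapply(rings, function(r) {
    length(r) >= 5L && length(r) <= 7L &&
      ring_all_aromatic(r, bond_df)
  }, logical(1)))

  # consistency: every aromatic atom must sit on a cycle of aromatic bonds
  arom_cycle_atoms <- unique(unlist(
    rings[vapply(rings, ring_all_aromatic, logical(1), bond_df = bond_df)]
  ))
  bad <- atom_df$index[atom_df$aromatic & !(atom_df$index %in%
                                              arom_cycle_atoms)]
  if (length(bad) > 0L) {
    smiles_error("aromaticity",
                 sprintf("aromatic atom(s) %s not on any aromatic ring",
                         paste(bad, collapse = ", ")),
                 atom_df$token_end[atom_df$index == bad[1]], smiles)
  }

  atom_df$implicit_h <- compute_implicit_h(atom_df, bond_df, smiles)

  structure(
    list(
      atoms = atom_df[, c("index", "element", "atomic_number",
                          "formal_charge", "aromatic", "explicit_h",
                          "implicit_h", "in_ring", "bracket", "token_end")],
      bonds = bond_df,
      rings = rings,
      aromatic_rings = aromatic_rings,
      source_smiles = smiles
    ),
    class = "molecular_graph"
  )
}

# bracket atom: [isotope? element chirality? Hn? charge?]
parse_bracket_atom <- function(chars, start, smiles) {
  i <- start + 1L
  n <- length(chars)
  # isotope
  while (i <= n && grepl("^[0-9]$", chars[i])) i <- i + 1L
  if (i > n) smiles_error("element", "unterminated bracket atom", start, smiles)
  # element symbol (two-letter first), aromatic lowercase allowed
  aromatic <- FALSE
  element <- NA_character_
  two <- if (i < n) paste0(chars[i], chars[i + 1L]) else ""
  if (two %in% names(.ATOMIC_NUMBER)) {
    element <- two; i <- i + 2L
  } else if (chars[i] %in% names(.ATOMIC_NUMBER)) {
    element <- chars[i]; i <- i + 1L
  } else if (chars[i] %in% .AROMATIC_TOKENS) {
    element <- toupper(chars[i]); aromatic <- TRUE; i <- i + 1L
  } else {
    smiles_error("element",
                 sprintf("unknown element token '%s' in bracket", chars[i]),
                 i, smiles)
  }
  # chirality markers, ignored
  while (i <= n && chars[i] == "@") i <- i + 1L
  # explicit hydrogens
  explicit_h <- 0L
  if (i <= n && chars[i] == "H") {
    i <- i + 1L
    if (i <= n && grepl("^[0-9]$", chars[i])) {
      explicit_h <- as.integer(chars[i]); i <- i + 1L
    } else {
      explicit_h <- 1L
    }
  }
  # charge
  charge <- 0L
  if (i <= n && chars[i] %in% c("+", "-")) {
    sign <- if (chars[i] == "+") 1L else -1L
    sym <- chars[i]
    i <- i + 1L
    if (i <= n && grepl("^[0-9]$", chars[i])) {
      charge <- sign * as.integer(chars[i]); i <- i + 1L
    } else {
      charge <- sign
      while (i <= n && chars[i] == sym) {
        charge <- charge + sign; i <- i + 1L
      }
    }
  }
  if (i > n || chars[i] != "]") {
    smiles_error("element", "unterminated or malformed bracket atom",
                 min(i, n), smiles)
  }
  list(element = element, aromatic = aromatic, charge = charge,
       explicit_h = explicit_h, next_i = i + 1L)
}

# implicit hydrogen assignment; raises valence-deficit errors
compute_implicit_h <- function(atom_df, bond_df, smiles) {
  n <- nrow(atom_df)
  implicit_h <- integer(n)
  for (k in seq_len(n)) {
    if (atom_df$bracket[k]) next  # bracket atoms: H count is explicit only
    el <- atom_df$element[k]
    idx0 <- atom_df$index[k]
    rows <- bond_df$atom_a == idx0 | bond_df$atom_b == idx0
    orders <- bond_df$order_code[rows]
    if (atom_df$aromatic[k]) {
      base_sum <- sum(ifelse(orders == 4L, 1L, orders))
      bond_sum <- base_sum + 1L  # delocalized-system increment
    } else {
      bond_sum <- sum(ifelse(orders == 4L, 1L, orders))
      base_sum <- bond_sum
    }
    allowed <- .ALLOWED_VALENCES[[el]]
    charge <- atom_df$formal_charge[k]
    if (el %in% c("N", "P")) {
      allowed <- allowed + charge
    } else if (el %in% c("O", "S") && charge < 0) {
      allowed <- allowed - abs(charge)
    }
    allowed <- allowed[allowed >= 0]
    if (atom_df$aromatic[k] && bond_sum > max(allowed) &&
        base_sum <= max(allowed)) {
      # lone-pair donor heteroatom (furan O, thiophene S): no extra unit
      bond_sum <- base_sum
    }
    fitting <- allowed[allowed >= bond_sum]
    if (length(fitting) == 0L) {
      smiles_error("valence",
                   sprintf("valence deficit on atom %d (%s): bond sum %d exceeds maximum valence %d",
                           idx0, el, bond_sum, max(allowed)),
                   atom_df$token_end[k], smiles)
    }
    implicit_h[k] <- as.integer(min(fitting) - bond_sum)
  }
  implicit_h
}

# Cycle detection ---------------------------------------------------------

adjacency_list <- function(n_atoms, bond_df) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(n_atoms)) adj[[k]] <- integer()
  if (nrow(bond_df) > 0L) {
    for (k in seq_len(nrow(bond_df))) {
      a <- bond_df$atom_a[k] + 1L
      b <- bond_df$atom_b[k] + 1L
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# smallest cycle through each non-tree edge (0-based atom indices out)
find_rings <- function(n_atoms, bond_df) {
  if (nrow(bond_df) == 0L) return(list())
  adj <- adjacency_list(n_atoms, bond_df)
  # spanning forest by BFS
  visited <- logical(n_atoms)
  tree_edge <- matrix(FALSE, nrow(bond_df), 1)
  edge_index <- function(a, b) {
    which((bond_df$atom_a == a - 1L & bond_df$atom_b == b - 1L) |
            (bond_df$atom_a == b - 1L & bond_df$atom_b == a - 1L))[1]
  }
  for (root in seq_len(n_atoms)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue) > 0L) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!visited[v]) {
          visited[v] <- TRUE
          tree_edge[edge_index(u, v), 1] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
  }
  rings <- list()
  seen <- character()
  for (k in which(!tree_edge[, 1])) {
    a <- bond_df$atom_a[k] + 1L
    b <- bond_df$atom_b[k] + 1L
    path <- bfs_path_excluding(adj, a, b, exclude = c(a, b))
    if (is.null(path)) next
    cycle <- path - 1L  # includes both endpoints
    key <- paste(sort(cycle), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- cycle
    }
  }
  rings
}

# shortest path a..b not using the direct edge a-b (1-based in/out)
bfs_path_excluding <- function(adj, a, b, exclude) {
  n <- length(adj)
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  visited[a] <- TRUE
  queue <- a
  while (length(queue) > 0L) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (u == a && v == b) next  # skip the closing edge itself
      if (!visited[v]) {
        visited[v] <- TRUE
        parent[v] <- u
        if (v == b) {
          path <- v
          while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, v)
      }
    }
  }
  NULL
}

bond_in_some_ring <- function(a, b, rings) {
  for (r in rings) {
    pos_a <- match(a, r)
    pos_b <- match(b, r)
    if (!is.na(pos_a) && !is.na(pos_b)) {
      len <- length(r)
      if (abs(pos_a - pos_b) == 1L || abs(pos_a - pos_b) == len - 1L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

ring_all_aromatic <- function(ring, bond_df) {
  len <- length(ring)
  if (len < 3L) return(FALSE)
  for (k in seq_len(len)) {
    a <- ring[k]
    b <- ring[if (k == len) 1L else k + 1L]
    row <- (bond_df$atom_a == a & bond_df$atom_b == b) |
      (bond_df$atom_a == b & bond_df$atom_b == a)
    if (!any(row) || bond_df$order_code[which(row)[1]] != 4L) return(FALSE)
  }
  TRUE
}

#' Topological distance matrix of a molecular graph
#'
#' Shortest-path distances in bond counts between all atom pairs, by
#' breadth-first search. Atoms in different disconnected components get
#' `Inf`.
#'
#' @param graph A `molecular_graph` from [parse_smiles()].
#' @return A symmetric numeric matrix (n_atoms x n_atoms) with zero
#'   diagonal; entry `[i, j]` is the bond-count distance between atoms
#'   `i - 1` and `j - 1` (atom indices are 0-based, matrix is 1-based).
#' @examples
#' topological_distances(parse_smiles("CCO"))[1, 3]  # 2
#' @export
topological_distances <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- nrow(graph$atoms)
  adj <- adjacency_list(n, graph$bonds)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue) > 0L) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(d[s, v])) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}

#' Ring perception results for a molecular graph
#'
#' Returns the small rings found by cycle perception (one smallest cycle
#' per independent cycle of the graph) and which of them are aromatic:
#' rings of size 5-7 whose bonds are all aromatic.
#'
#' @param graph A `molecular_graph`.
#' @return A list with `rings` (list of integer vectors of 0-based atom
#'   indices, each an atom cycle) and `aromatic_rings` (integer indices
#'   into `rings`).
#' @examples
#' ring_info(parse_smiles("c1ccc2ccccc2c1"))
#' @export
ring_info <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  list(rings = graph$rings, aromatic_rings = graph$aromatic_rings)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s\n", x$source_smiles))
  cat(sprintf("  %d heavy atoms, %d bonds, %d ring(s) (%d aromatic)\n",
              nrow(x$atoms), nrow(x$bonds), length(x$rings),
              length(x$aromatic_rings)))
  invisible(x)
}

# total hydrogen count per atom (explicit bracket H + derived implicit H)
total_h <- function(graph) {
  eh <- pmax(graph$atoms$explicit_h, 0L)
  eh + graph$atoms$implicit_h
}

heavy_degree <- function(graph) {
  n <- nrow(graph$atoms)
  deg <- integer(n)
  if (nrow(graph$bonds) > 0L) {
    tab <- table(factor(c(graph$bonds$atom_a, graph$bonds$atom_b),
                        levels = 0:(n - 1L)))
    deg <- as.integer(tab)
  }
  deg
}
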