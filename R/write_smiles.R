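# SMILES output ------------------------------------------------------------
#
# Depth-first writer used to re-serialize a graph from an arbitrary root
# atom and branch order. Its purpose is round-trip testing (fingerprints
# must be invariant to how a structure is written), not canonicalization:
# two calls with different roots give different, equally valid strings.

atom_token <- function(graph, k) {
  el <- graph$atoms$element[k]
  aromatic <- graph$atoms$aromatic[k]
  charge <- graph$atoms$formal_charge[k]
  explicit_h <- graph$atoms$explicit_h[k]
  bracket <- graph$atoms$bracket[k] || charge != 0L
  sym <- if (aromatic) tolower(el) else el
  if (!bracket) return(sym)
  h <- if (explicit_h > 0L) {
    if (explicit_h == 1L) "H" else paste0("H", explicit_h)
  } else ""
  chg <- if (charge > 0L) {
    if (charge == 1L) "+" else paste0("+", charge)
  } else if (charge < 0L) {
    if (charge == -1L) "-" else paste0("-", abs(charge))
  } else ""
  paste0("[", sym, h, chg, "]")
}

bond_token <- function(graph, a, b, order) {
  if (order == 2L) return("=")
  if (order == 3L) return("#")
  if (order == 4L) {
    both_arom <- graph$atoms$aromatic[a] && graph$atoms$aromatic[b]
    return(if (both_arom) "" else ":")
  }
  # explicit single needed between two aromatic atoms (biaryl link)
  if (graph$atoms$aromatic[a] && graph$atoms$aromatic[b]) "-" else ""
}

# re-serialize `graph` starting from `root` (1-based atom); `shuffle`
# randomizes branch order (caller controls the RNG)
write_smiles <- function(graph, root = 1L, shuffle = FALSE) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- nrow(graph$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$atom_a[k] + 1L
    b <- graph$bonds$atom_b[k] + 1L
    o <- graph$bonds$order_code[k]
    adj[[a]] <- rbind(adj[[a]], c(b, o))
    adj[[b]] <- rbind(adj[[b]], c(a, o))
  }
  if (shuffle) {
    adj <- lapply(adj, function(m) {
      if (is.null(m) || nrow(m) == 1L) m else
        m[sample.int(nrow(m)), , drop = FALSE]
    })
  }

  # phase 1: DFS to fix visit order, tree edges, and ring-closure tokens
  visited <- logical(n)
  closure <- vector("list", n)            # tokens each atom must print
  for (k in seq_len(n)) closure[[k]] <- character()
  tree_kids <- vector("list", n)          # (child, order) rows, DFS order
  seen_edge <- new.env()
  n_labels <- 0L
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  walk <- function(a, par) {
    visited[a] <<- TRUE
    kids <- adj[[a]]
    if (is.null(kids)) return(invisible())
    for (r in seq_len(nrow(kids))) {
      b <- kids[r, 1]; o <- kids[r, 2]
      if (!is.na(par) && b == par && is.null(seen_edge[[edge_key(a, b)]])) {
        seen_edge[[edge_key(a, b)]] <- TRUE
        next
      }
      key <- edge_key(a, b)
      if (visited[b]) {
        if (is.null(seen_edge[[key]])) {   # back edge -> ring closure
          seen_edge[[key]] <- TRUE
          n_labels <<- n_labels + 1L
          label <- if (n_labels <= 9L) as.character(n_labels) else
            sprintf("%%%02d", n_labels)
          tok <- paste0(bond_token(graph, a, b, o), label)
          closure[[a]] <<- c(closure[[a]], tok)
          closure[[b]] <<- c(closure[[b]], tok)
        }
      } else {
        seen_edge[[key]] <- TRUE
        tree_kids[[a]] <<- rbind(tree_kids[[a]], c(b, o))
        walk(b, a)
      }
    }
    invisible()
  }
  comp_roots <- integer()
  walk(root, NA_integer_)
  for (s in seq_len(n)) {
    if (!visited[s]) { comp_roots <- c(comp_roots, s); walk(s, NA_integer_) }
  }

  # phase 2: emit along the frozen spanning tree
  emit <- function(a) {
    out <- paste0(atom_token(graph, a), paste(closure[[a]], collapse = ""))
    kids <- tree_kids[[a]]
    if (!is.null(kids)) {
      branches <- vapply(seq_len(nrow(kids)), function(r) {
        paste0(bond_token(graph, a, kids[r, 1], kids[r, 2]),
               emit(kids[r, 1]))
      }, character(1))
      if (length(branches) > 1L) {
        out <- paste0(out,
                      paste0("(", branches[-length(branches)], ")",
                             collapse = ""),
                      branches[length(branches)])
      } else {
        out <- paste0(out, branches)
      }
    }
    out
  }
  paste(vapply(c(root, comp_roots), emit, character(1)), collapse = ".")
}
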