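#' Write / read coalescence records as tab-delimited text
#'
#' One record per line with fields left, right, node, child1, child2, time,
#' separated by tabs.  Times are rendered with 17 significant digits (the
#' shortest representation that round-trips an IEEE double), so
#' \code{read_records_text(write_records_text(ts))} reproduces the tree
#' sequence exactly.
#'
#' @param ts a \code{tree_sequence}.
#' @param file path or connection to write to / read from.
#' @return \code{write_records_text} returns \code{file} invisibly;
#'   \code{read_records_text} returns a \code{tree_sequence}.  The sample
#'   size is recovered from the records (the leaves are exactly the labels
#'   that never occur as a parent) and \code{m} as the largest right
#'   coordinate, unless given explicitly.
#' @examples
#' ts <- sim_coalescent(4, m = 20, rho = 1, seed = 5)
#' f <- tempfile()
#' write_records_text(ts, f)
#' identical(read_records_text(f)$records, ts$records)
#' @export
write_records_text <- function(ts, file) {
  stopifnot(inherits(ts, "tree_sequence"))
  r <- ts$records
  lines <- sprintf("%d\t%d\t%d\t%d\t%d\t%s", r$left, r$right, r$node,
                   r$child1, r$child2, shortest_repr(r$time))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_records_text
#' @param n,m sample size and sequence length; inferred from the records
#'   when NULL.
#' @export
read_records_text <- function(file, n = NULL, m = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    ts_error("no records: empty record text is not a valid tree sequence",
             "treeseq_parse_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 6L)
  if (length(bad) > 0L)
    ts_error(sprintf("malformed record on line %d: expected 6 tab-separated fields",
                     bad[1]), "treeseq_parse_error")
  fields <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  num <- suppressWarnings(apply(fields, 2L, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, ncol = 6L)
  badnum <- which(apply(is.na(num), 1L, any))
  if (length(badnum) > 0L)
    ts_error(sprintf("malformed record on line %d: non-numeric field",
                     badnum[1]), "treeseq_parse_error")
  records <- data.frame(left = as.integer(num[, 1]),
                        right = as.integer(num[, 2]),
                        node = as.integer(num[, 3]),
                        child1 = as.integer(num[, 4]),
                        child2 = as.integer(num[, 5]),
                        time = num[, 6])
  if (is.null(n)) {
    children <- unique(c(records$child1, records$child2))
    n <- max(setdiff(children, records$node))
  }
  if (is.null(m)) m <- max(records$right)
  tree_sequence(records, n, m)
}

h5_format_version <- 1L

# shortest decimal representation that parses back to the same double
shortest_repr <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Write / read a tree sequence as an HDF5 container
#'
#' Stores the record columns (and optionally mutations) in a structured
#' binary container: group \code{/records} holds datasets \code{left},
#' \code{right}, \code{node}, \code{children} (a 2 x M matrix) and
#' \code{time}; \code{/mutations} holds \code{node} and \code{position};
#' \code{/metadata} holds \code{n}, \code{m} and \code{format_version}.
#' Integer columns are 32-bit, times and positions 64-bit floats; the
#' round-trip is lossless.  With \code{compress = TRUE} datasets are
#' written with zlib (deflate level 6) compression.
#'
#' @param ts a \code{tree_sequence}.
#' @param file path of the container file.
#' @param mutations optional mutation data.frame ([sim_mutations()]).
#' @param compress use zlib compression (default TRUE).
#' @return \code{write_treeseq_h5} returns \code{file} invisibly;
#'   \code{read_treeseq_h5} returns a list with elements \code{ts} and
#'   \code{mutations} (NULL when absent).
#' @export
write_treeseq_h5 <- function(ts, file, mutations = NULL, compress = TRUE) {
  stopifnot(inherits(ts, "tree_sequence"))
  if (file.exists(file)) unlink(file)
  level <- if (compress) 6L else 0L
  rhdf5::h5createFile(file)
  rhdf5::h5createGroup(file, "metadata")
  rhdf5::h5createGroup(file, "records")
  r <- ts$records
  M <- nrow(r)
  wrD <- function(name, data, dims, storage) {
    rhdf5::h5createDataset(file, name, dims = dims,
                           storage.mode = storage, level = level,
                           chunk = dims)
    rhdf5::h5write(data, file, name)
  }
  rhdf5::h5write(ts$n, file, "metadata/n")
  rhdf5::h5write(ts$m, file, "metadata/m")
  rhdf5::h5write(h5_format_version, file, "metadata/format_version")
  wrD("records/left", r$left, M, "integer")
  wrD("records/right", r$right, M, "integer")
  wrD("records/node", r$node, M, "integer")
  wrD("records/children", rbind(r$child1, r$child2), c(2L, M), "integer")
  wrD("records/time", r$time, M, "double")
  if (!is.null(mutations) && nrow(mutations) > 0L) {
    rhdf5::h5createGroup(file, "mutations")
    wrD("mutations/node", as.integer(mutations$node), nrow(mutations),
        "integer")
    wrD("mutations/position", as.numeric(mutations$position),
        nrow(mutations), "double")
  }
  rhdf5::h5closeAll()
  invisible(file)
}

#' @rdname write_treeseq_h5
#' @export
read_treeseq_h5 <- function(file) {
  if (!file.exists(file))
    ts_error(sprintf("no such file: %s", file), "treeseq_parse_error")
  contents <- rhdf5::h5ls(file)
  version <- tryCatch(as.integer(rhdf5::h5read(file, "metadata/format_version")),
                      error = function(e) NA_integer_)
  if (is.na(version))
    ts_error("missing metadata/format_version", "treeseq_parse_error")
  if (version != h5_format_version)
    ts_error(sprintf("container format version %d not supported (expected %d)",
                     version, h5_format_version), "treeseq_parse_error")
  rd <- function(name) {
    tryCatch(rhdf5::h5read(file, name),
             error = function(e)
               ts_error(sprintf("missing dataset %s", name),
                        "treeseq_parse_error"))
  }
  n <- as.integer(rd("metadata/n"))
  m <- as.integer(rd("metadata/m"))
  children <- rd("records/children")
  records <- data.frame(
    left = as.integer(rd("records/left")),
    right = as.integer(rd("records/right")),
    node = as.integer(rd("records/node")),
    child1 = as.integer(children[1, ]),
    child2 = as.integer(children[2, ]),
    time = as.numeric(rd("records/time")))
  mutations <- NULL
  if (any(contents$name == "mutations" & contents$otype == "H5I_GROUP")) {
    mutations <- data.frame(node = as.integer(rd("mutations/node")),
                            position = as.numeric(rd("mutations/position")))
  }
  rhdf5::h5closeAll()
  list(ts = tree_sequence(records, n, m), mutations = mutations)
}

#' Render a sparse tree in Newick format
#'
#' Leaves are labelled \code{1..n}; internal nodes are unlabelled.  Branch
#' lengths are differences of node times (time of parent minus time of
#' child) rendered with \code{precision} significant digits -- note this is
#' the only lossy serialisation in the package, which is why the native
#' formats store node times rather than branch lengths.  Children are
#' emitted in ascending label order, and multifurcating nodes are
#' supported.
#'
#' @param tree a \code{sparse_tree}.
#' @param times numeric vector of node times indexed by label
#'   (see [node_times()]).
#' @param precision significant digits for branch lengths (default 6).
#' @return a single Newick string terminated by \code{";"}.
#' @examples
#' ts <- tree_sequence(coalescence_records(0, 1, 3L, 1L, 2L, 0.5), n = 2, m = 1)
#' tree_newick(build_tree_at(ts, 0), node_times(ts))  # "(1:0.5,2:0.5);"
#' @export
tree_newick <- function(tree, times, precision = 6L) {
  stopifnot(inherits(tree, "sparse_tree"))
  root <- tree_root(tree)
  if (length(times) < max(tree_nodes(tree)) || anyNA(times[tree_nodes(tree)]))
    ts_error("node times missing for Newick output", "treeseq_structure_error")
  kids <- children_list(tree)
  fmt <- function(x) sprintf("%.*g", precision, x)
  render <- function(u) {
    if (u <= tree$n) as.character(u)
    else paste0("(", paste(vapply(kids[[u]], function(v)
      paste0(render(v), ":", fmt(times[u] - times[v])), character(1)),
      collapse = ","), ")")
  }
  paste0(render(root), ";")
}

#' Write replicate simulations in ms-style text
#'
#' Emits the classic text layout: each replicate starts with \code{"//"};
#' with \code{trees = TRUE} one line per marginal tree follows, the Newick
#' string prefixed by its span in sites (\code{[span]...}); with mutations
#' present a \code{segsites:} line, a \code{positions:} line (positions
#' rescaled to \code{[0, 1)}) and one 0/1 haplotype row per sample.
#'
#' @param replicates a list; each element is a list with elements \code{ts}
#'   and optionally \code{mutations}.
#' @param file path or connection; NULL to only return the lines.
#' @param trees emit per-tree Newick lines.
#' @param precision significant digits for Newick branch lengths.
#' @return the character vector of emitted lines, invisibly.
#' @export
write_ms_style <- function(replicates, file = stdout(), trees = FALSE,
                           precision = 6L) {
  out <- character(0)
  for (rep in replicates) {
    ts <- rep$ts
    out <- c(out, "//")
    if (trees) {
      times <- node_times(ts)
      lines <- character(0)
      iterate_trees(ts, function(tree) {
        span <- tree$interval[2] - tree$interval[1]
        lines[[length(lines) + 1L]] <<-
          paste0("[", span, "]", tree_newick(tree, times, precision))
      })
      out <- c(out, lines)
    }
    if (!is.null(rep$mutations)) {
      mut <- rep$mutations[order(rep$mutations$position), , drop = FALSE]
      out <- c(out, sprintf("segsites: %d", nrow(mut)))
      if (nrow(mut) > 0L) {
        out <- c(out,
                 paste("positions:",
                       paste(sprintf("%.6f", mut$position / ts$m),
                             collapse = " ")),
                 apply(haplotypes(ts, mut), 1L, paste, collapse = ""))
      }
    }
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
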