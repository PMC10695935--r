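# File formats. Vertex ids are 0-based in all text files (and converted to
# the package's internal 1-based indexing on read).
#
#  * dense observations: whitespace- or comma-separated n x n integer matrix
#  * sparse observations: lines "i j count"; absent pairs count 0
#  * structures: one hyperedge per line, 2 or 3 vertex ids; categorical
#    graphs prefix each line with "w" (weak) or "s" (strong); "#" comments;
#    an optional "# n=<N>" header records the vertex count
#  * chains: JSON-lines, one record per retained sample

read_noncomment_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  list(lines = lines[idx], numbers = idx, all = lines)
}

parse_count <- function(tok, lineno, path) {
  v <- suppressWarnings(as.numeric(tok))
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop(sprintf("%s, line %d: counts must be nonnegative integers", path,
                 lineno))
  }
  as.integer(v)
}

#' Read a pairwise observation matrix
#'
#' Accepts a dense square symmetric integer matrix (whitespace or
#' comma-separated) or a sparse file with "i j count" lines and 0-based
#' vertex ids. With `format = "auto"`, a table with exactly three columns and
#' a shape inconsistent with a symmetric matrix is treated as sparse.
#'
#' @param path Path to the file.
#' @param n For sparse files, the number of vertices (otherwise inferred as
#'   `max id + 1`).
#' @param format `"auto"`, `"dense"` or `"sparse"`.
#' @return A symmetric integer matrix.
#' @export
read_observations <- function(path, n = NULL, format = c("auto", "dense",
                                                         "sparse")) {
  format <- match.arg(format)
  src <- read_noncomment_lines(path)
  if (!length(src$lines)) stop(path, ": no data lines")
  rows <- strsplit(gsub(",", " ", trimws(src$lines)), "\\s+")
  ncols <- lengths(rows)
  if (format == "auto") {
    # a square table is read as dense; anything else as sparse triplets
    # (3 x 3 tables are ambiguous -- pass format explicitly to force sparse)
    format <- if (length(unique(ncols)) == 1L && ncols[1] == length(rows)) {
      "dense"
    } else {
      "sparse"
    }
  }
  if (format == "dense") {
    if (length(unique(ncols)) != 1L || ncols[1] != length(rows)) {
      stop(path, ": dense observation matrix must be square")
    }
    X <- t(vapply(seq_along(rows), function(r) {
      parse_count(rows[[r]], src$numbers[r], path)
    }, integer(ncols[1])))
    diag(X) <- 0L
    if (any(X != t(X))) stop(path, ": dense observation matrix not symmetric")
    X
  } else {
    if (any(ncols != 3L)) {
      bad <- src$numbers[which(ncols != 3L)[1]]
      stop(sprintf("%s, line %d: sparse entries must be 'i j count'", path,
                   bad))
    }
    m <- t(vapply(seq_along(rows), function(r) {
      parse_count(rows[[r]], src$numbers[r], path)
    }, integer(3)))
    if (is.null(n)) n <- max(m[, 1:2]) + 1L
    if (any(m[, 1:2] >= n)) stop(path, ": vertex id exceeds n")
    if (any(m[, 1] == m[, 2])) stop(path, ": self-pairs not allowed")
    X <- matrix(0L, n, n)
    X[cbind(m[, 1], m[, 2]) + 1L] <- m[, 3]
    X[cbind(m[, 2], m[, 1]) + 1L] <- m[, 3]
    X
  }
}

#' Write a pairwise observation matrix
#'
#' @param X Symmetric integer matrix.
#' @param path Output path.
#' @param format `"dense"` (full matrix, zero diagonal) or `"sparse"`
#'   ("i j count" lines for nonzero pairs, 0-based ids).
#' @export
write_observations <- function(X, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  check_observations(X)
  X <- X
  diag(X) <- 0L
  if (format == "dense") {
    write.table(X, path, row.names = FALSE, col.names = FALSE)
  } else {
    P <- all_pairs(nrow(X))
    x <- X[P]
    keep <- x > 0L
    df <- cbind(P[keep, , drop = FALSE] - 1L, x[keep])
    writeLines(c(sprintf("# n=%d", nrow(X)),
                 apply(df, 1L, paste, collapse = " ")), path)
  }
  invisible(path)
}

#' Read a latent structure from a hyperedge-list file
#'
#' Lines with two or three 0-based vertex ids denote 2-edges and 3-edges of a
#' hypergraph; lines prefixed `w`/`s` denote weak/strong edges of a
#' categorical-edges graph. Duplicate hyperedges are dropped with a warning.
#'
#' @param path Path to the file.
#' @param n Vertex count; defaults to a `# n=<N>` header if present, else
#'   `max id + 1`.
#' @return A [hypergraph()] or [categorical_graph()].
#' @export
read_structure <- function(path, n = NULL) {
  src <- read_noncomment_lines(path)
  header <- grep("^#\\s*n\\s*=\\s*\\d+", src$all, value = TRUE)
  if (is.null(n) && length(header)) {
    n <- as.integer(sub(".*=\\s*", "", header[1]))
  }
  toks <- strsplit(trimws(src$lines), "\\s+")
  is_graph <- length(toks) > 0L &&
    any(vapply(toks, function(t) t[1] %in% c("w", "s"), logical(1)))
  parse_ids <- function(t, lineno) {
    v <- suppressWarnings(as.integer(t))
    if (anyNA(v) || any(v < 0)) {
      stop(sprintf("%s, line %d: malformed hyperedge", path, lineno))
    }
    v
  }
  if (is_graph) {
    weak <- list(); strong <- list()
    for (r in seq_along(toks)) {
      t <- toks[[r]]
      if (length(t) != 3L || !(t[1] %in% c("w", "s"))) {
        stop(sprintf("%s, line %d: expected 'w i j' or 's i j'", path,
                     src$numbers[r]))
      }
      ids <- parse_ids(t[-1], src$numbers[r])
      if (t[1] == "w") weak[[length(weak) + 1L]] <- ids
      else strong[[length(strong) + 1L]] <- ids
    }
    E1 <- do.call(rbind, weak)
    E2 <- do.call(rbind, strong)
    if (is.null(n)) n <- max(c(unlist(weak), unlist(strong), -1L)) + 1L
    dedup_warn(length(weak) + length(strong), E1, E2, n, path)
    categorical_graph(n, weak = if (!is.null(E1)) E1 + 1L,
                      strong = if (!is.null(E2)) E2 + 1L)
  } else {
    edges <- list(); triples <- list()
    for (r in seq_along(toks)) {
      ids <- parse_ids(toks[[r]], src$numbers[r])
      if (length(ids) == 2L) edges[[length(edges) + 1L]] <- ids
      else if (length(ids) == 3L) triples[[length(triples) + 1L]] <- ids
      else stop(sprintf("%s, line %d: hyperedges must have 2 or 3 vertices",
                        path, src$numbers[r]))
    }
    E <- do.call(rbind, edges)
    Tm <- do.call(rbind, triples)
    if (is.null(n)) n <- max(c(unlist(edges), unlist(triples), -1L)) + 1L
    dedup_warn(length(edges) + length(triples), E, Tm, n, path)
    hypergraph(n, edges = if (!is.null(E)) E + 1L,
               triples = if (!is.null(Tm)) Tm + 1L)
  }
}

dedup_warn <- function(n_lines, A, B, n, path) {
  kept <- 0L
  for (m in list(A, B)) {
    if (is.null(m)) next
    kept <- kept + nrow(unique(t(apply(m, 1L, sort.int))))
  }
  if (kept < n_lines) {
    warning(path, ": duplicate hyperedges dropped", call. = FALSE)
  }
  invisible(NULL)
}

#' Write a latent structure to a hyperedge-list file
#'
#' @param S A [hypergraph()] or [categorical_graph()].
#' @param path Output path.
#' @export
write_structure <- function(S, path) {
  lines <- sprintf("# n=%d", S$n)
  fmt <- function(m, prefix = NULL) {
    if (nrow(m) == 0L) return(character(0))
    body <- apply(m - 1L, 1L, paste, collapse = " ")
    if (is.null(prefix)) body else paste(prefix, body)
  }
  if (inherits(S, "hypergraph")) {
    lines <- c(lines, fmt(S$edges), fmt(S$triples))
  } else if (inherits(S, "categorical_graph")) {
    lines <- c(lines, fmt(S$weak, "w"), fmt(S$strong, "s"))
  } else {
    stop("S must be a hypergraph or categorical_graph")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a posterior chain as JSON-lines
#'
#' One JSON record per retained sample, with the structure's hyperedge lists
#' (0-based ids), `mu`, `phi`, `log_posterior` and the sweep index.
#'
#' @param chain A `hyperchain` from [run_chain()].
#' @param path Output path.
#' @export
write_chain <- function(chain, path) {
  check_chain(chain)
  recs <- vapply(chain$samples, function(s) {
    rec <- list(
      model = chain$model, n = chain$n,
      mu = s$mu, phi = as.list(s$phi),
      log_posterior = s$log_posterior, sweep = s$sweep
    )
    if (chain$model == "hypergraph") {
      rec$edges <- unname(apply(s$structure$edges - 1L, 1L, c,
                                simplify = FALSE))
      rec$triples <- unname(apply(s$structure$triples - 1L, 1L, c,
                                  simplify = FALSE))
    } else {
      rec$weak <- unname(apply(s$structure$weak - 1L, 1L, c,
                               simplify = FALSE))
      rec$strong <- unname(apply(s$structure$strong - 1L, 1L, c,
                                 simplify = FALSE))
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(recs, path)
  invisible(path)
}

#' Read a posterior chain from JSON-lines
#'
#' @param path Path written by [write_chain()].
#' @return A `hyperchain`.
#' @export
read_chain <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(path, ": empty chain file")
  samples <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyMatrix = TRUE)
    to_mat <- function(x, w) {
      if (length(x) == 0L) matrix(integer(0), ncol = w)
      else if (is.matrix(x)) x + 1L
      else matrix(unlist(x), ncol = w, byrow = TRUE) + 1L
    }
    s <- list(mu = as.numeric(rec$mu), phi = unlist(rec$phi),
              log_posterior = rec$log_posterior, sweep = rec$sweep)
    if (identical(rec$model, "hypergraph")) {
      s$structure <- hypergraph(rec$n, edges = to_mat(rec$edges, 2L),
                                triples = to_mat(rec$triples, 3L))
    } else {
      s$structure <- categorical_graph(rec$n, weak = to_mat(rec$weak, 2L),
                                       strong = to_mat(rec$strong, 2L))
    }
    s[c("structure", "mu", "phi", "log_posterior", "sweep")]
  })
  model <- jsonlite::fromJSON(lines[1])$model
  n <- jsonlite::fromJSON(lines[1])$n
  structure(list(model = model, samples = samples, config = NULL,
                 prior = NULL, n = n),
            class = "hyperchain")
}
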