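#' Read a data matrix from CSV/TSV
#'
#' Expects a header row of variable names and one observation per row. If
#' the first column is non-numeric it is treated as observation ids and
#' becomes the rownames.
#'
#' @param path file path; tab-delimited when the extension is `.tsv` or
#'   `.txt`, comma-delimited otherwise.
#' @return Numeric matrix with observation ids as rownames.
#' @export
read_data_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 0L || nrow(df) == 0L) stop("empty data file: ", path)
  if (!is.numeric(df[[1L]])) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- ids
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(colnames(df)[bad], collapse = ", "))
  as.matrix(df)
}

#' Write projection coordinates to CSV
#'
#' @param coords N x 2 coordinate matrix (rownames used as ids when
#'   present).
#' @param path output file.
#' @param mode the projection summary used, recorded per row.
#' @export
write_projection_csv <- function(coords, path, mode = "mean") {
  ids <- rownames(coords)
  if (is.null(ids)) ids <- paste0("obs", seq_len(nrow(coords)))
  utils::write.csv(data.frame(id = ids, q1 = coords[, 1L], q2 = coords[, 2L],
                              mode = mode),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write lattice magnification factors to CSV
#'
#' @param model a fitted `gtm`.
#' @param path output file with columns `j`, `r1`, `r2`, `factor`.
#' @export
write_magnification_csv <- function(model, path) {
  fac <- magnification(model)
  pts <- model$grid$points
  utils::write.csv(data.frame(j = seq_len(nrow(pts)), r1 = pts[, 1L],
                              r2 = pts[, 2L], factor = as.numeric(fac)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a GTM model to JSON
#'
#' Writes a single JSON document holding the lattice, basis, loadings
#' (row-major), noise precision, anchors, pins, the blended manifold when
#' present, fit controls, trace and the interaction log, sufficient to
#' restore the model with [load_gtm()].
#'
#' @param model a `gtm`.
#' @param path output file.
#' @export
save_gtm <- function(model, path) {
  doc <- list(
    format = "v2pigtm-model", version = 1L,
    grid = list(points = unclass(model$grid$points),
                shape = model$grid$shape, extent = model$grid$extent),
    basis = list(centers = unclass(model$basis$centers),
                 sigma2 = model$basis$sigma2, has_bias = model$basis$has_bias),
    W = unclass(model$W), beta = model$beta,
    blended = model$blended,
    Y = if (model$blended) unclass(model$Y) else NULL,
    anchors = model$anchors,
    pin_obs = model$pin_obs, pin_col = model$pin_col,
    var_names = model$var_names, obs_ids = model$obs_ids,
    control = unclass(model$control),
    trace = model$trace, converged = model$converged,
    iterations = model$iterations,
    log = model$log)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a GTM model from JSON
#'
#' @param path a file written by [save_gtm()].
#' @return A `gtm` model.
#' @export
load_gtm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "v2pigtm-model"))
    stop("not a v2pigtm model file: ", path)
  grid <- structure(list(points = as_matrix2(doc$grid$points, c("r1", "r2")),
                         shape = as.integer(doc$grid$shape),
                         extent = matrix(doc$grid$extent, 2L, 2L)),
                    class = "gtm_grid")
  basis <- structure(list(centers = as_matrix2(doc$basis$centers, c("r1", "r2")),
                          sigma2 = doc$basis$sigma2,
                          has_bias = isTRUE(doc$basis$has_bias)),
                     class = "gtm_basis")
  W <- as_matrix2(doc$W)
  Phi <- design_matrix(basis, grid$points)
  Y <- if (isTRUE(doc$blended)) as_matrix2(doc$Y) else Phi %*% W
  anchors <- doc$anchors
  if (is.data.frame(anchors)) anchors <- split_df_rows(anchors)
  ctl <- doc$control
  model <- structure(list(
    grid = grid, basis = basis, Phi = Phi, W = W, Y = Y, beta = doc$beta,
    anchors = if (is.null(anchors)) list() else anchors,
    pin_obs = as.integer(doc$pin_obs), pin_col = as.integer(doc$pin_col),
    blended = isTRUE(doc$blended),
    var_names = doc$var_names, obs_ids = doc$obs_ids,
    trace = as.numeric(doc$trace), converged = doc$converged,
    iterations = doc$iterations,
    control = gtm_control(ctl$max_iter, ctl$rel_tol, ctl$ridge, ctl$seed),
    log = doc$log), class = "gtm")
  model
}

as_matrix2 <- function(x, cols = NULL) {
  m <- as.matrix(x)
  dimnames(m) <- if (is.null(cols)) NULL else list(NULL, cols)
  m
}

split_df_rows <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))

#' Read / write term-document counts
#'
#' Dense format: CSV whose first column (`term`) holds the vocabulary and
#' whose remaining header names are document ids. Triplet format: TSV with
#' columns `term`, `doc`, `count` listing nonzero cells.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.tsv` means triplet), `"dense"`
#'   or `"triplet"`.
#' @return Terms x documents numeric matrix.
#' @export
read_counts <- function(path, format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "triplet" else "dense"
  if (format == "dense") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    terms <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- terms
    m
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("term", "doc", "count") %in% names(df)))
      stop("triplet file needs columns term, doc, count: ", path)
    terms <- sort(unique(df$term))
    docs <- unique(df$doc)
    m <- matrix(0, length(terms), length(docs), dimnames = list(terms, docs))
    m[cbind(match(df$term, terms), match(df$doc, docs))] <- df$count
    m
  }
}

#' @rdname read_counts
#' @param counts terms x documents matrix to write.
#' @export
write_counts <- function(counts, path, format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "triplet" else "dense"
  counts <- as.matrix(counts)
  if (format == "dense") {
    df <- data.frame(term = rownames(counts), counts, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    nz <- which(counts != 0, arr.ind = TRUE)
    df <- data.frame(term = rownames(counts)[nz[, 1L]],
                     doc = colnames(counts)[nz[, 2L]],
                     count = counts[nz])
    df <- df[order(df$term, df$doc), ]
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write an interaction script (JSONL)
#'
#' One JSON record per line, each describing a move:
#' `{"obs_id": ..., "target": [a, b], "stage": 3, "family": "delta3",
#'   "h": 20}` (`"neighbors"` may replace `"h"`).
#'
#' @param path file path.
#' @return List of move records.
#' @export
read_moves <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("%s line %d: malformed JSON (%s)",
                                   path, i, conditionMessage(e))))
    rec
  })
}

#' @rdname read_moves
#' @param moves list of move records.
#' @export
write_moves <- function(moves, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in moves)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Write a tag or keyword result as JSON
#'
#' @param x a `gtm_tag` or `cluster_keywords` object.
#' @param path output file.
#' @export
write_insight_json <- function(x, path) {
  doc <- if (inherits(x, "gtm_tag")) {
    list(r_plus = x$r_plus,
         terms = lapply(seq_len(nrow(x$top_terms)), function(i)
           list(term = x$top_terms$term[i], score = x$top_terms$score[i])))
  } else if (inherits(x, "cluster_keywords")) {
    list(clusters = lapply(x$clusters, function(df)
           lapply(seq_len(nrow(df)), function(i)
             list(term = df$term[i], score = df$score[i]))),
         shared = x$shared)
  } else stop("unsupported object")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
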