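#' Construct a connectivity record
#'
#' A connectivity record holds one participant-by-condition symmetric weighted
#' functional-connectivity matrix (entries may be negative, diagonal zero)
#' plus its cohort metadata.
#'
#' @param matrix N x N numeric matrix, symmetric up to \code{tol}, where N is
#'   the node-table size. Asymmetry at or below \code{tol} is symmetrized as
#'   \code{(W + t(W))/2}; the diagonal is forced to zero.
#' @param participant_id,dataset_id,condition,age cohort metadata; condition
#'   must be \code{"fear"} or \code{"neutral"}.
#' @param node_table the \code{node_table} fixing N and node order.
#' @param tol symmetry tolerance (max absolute \code{W - t(W)}).
#' @return object of class \code{"connectivity_record"}: a list with elements
#'   \code{matrix}, \code{participant_id}, \code{dataset_id}, \code{condition},
#'   \code{age}.
#' @export
connectivity_record <- function(matrix, participant_id, dataset_id, condition,
                                age, node_table, tol = 1e-6) {
  n <- n_nodes(node_table)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("connectivity matrix must be numeric", call. = FALSE)
  if (nrow(matrix) != ncol(matrix))
    stop("connectivity matrix must be square, got ",
         nrow(matrix), " x ", ncol(matrix), call. = FALSE)
  if (nrow(matrix) != n)
    stop("matrix dimension ", nrow(matrix), " does not match node table (",
         n, " nodes)", call. = FALSE)
  if (anyNA(matrix))
    stop("connectivity matrix contains missing values", call. = FALSE)
  asym <- max(abs(matrix - t(matrix)))
  if (asym > tol)
    stop("matrix asymmetry ", format(asym), " exceeds tolerance ", format(tol),
         call. = FALSE)
  w <- (matrix + t(matrix)) / 2
  diag(w) <- 0
  condition <- match.arg(condition, c("fear", "neutral"))
  structure(
    list(matrix = w, participant_id = as.character(participant_id),
         dataset_id = as.character(dataset_id), condition = condition,
         age = as.numeric(age)),
    class = "connectivity_record"
  )
}

#' @export
print.connectivity_record <- function(x, ...) {
  cat(sprintf("<connectivity_record> %s / %s / %s (age %.1f), %d x %d\n",
              x$participant_id, x$dataset_id, x$condition, x$age,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else if (grepl(",", first, fixed = TRUE)) "," else " "
}

#' Read one connectivity matrix file
#'
#' Matrix files are plain delimited text (tab or comma, autodetected), no
#' header, one square matrix per file; node order is defined by the node
#' table, not the file.
#'
#' @param path matrix file.
#' @param node_table the \code{node_table} fixing dimension and node order.
#' @param meta a one-row data.frame (a cohort-manifest row) with
#'   \code{participant_id}, \code{dataset_id}, \code{age}; plus a
#'   \code{condition} argument below.
#' @param condition \code{"fear"} or \code{"neutral"}.
#' @param tol symmetry tolerance.
#' @return a \code{connectivity_record}.
#' @export
read_connectivity <- function(path, node_table, meta, condition, tol = 1e-6) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "numeric", strip.white = TRUE)
  m <- as.matrix(raw)
  dimnames(m) <- NULL
  connectivity_record(m, meta$participant_id, meta$dataset_id, condition,
                      meta$age, node_table, tol = tol)
}

#' Write a connectivity matrix file
#'
#' Writes the record's matrix as headerless tab-delimited text at full
#' precision (round-trips through [read_connectivity()] exactly).
#'
#' @param record a \code{connectivity_record} or a plain numeric matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_connectivity <- function(record, path) {
  m <- if (inherits(record, "connectivity_record")) record$matrix else record
  lines <- apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' The manifest is a CSV with header
#' \code{participant_id,dataset_id,age,path_fear,path_neutral}; one row per
#' participant, each with both condition files. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest CSV.
#' @return \code{read_manifest}: data.frame with the five columns above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "dataset_id", "age", "path_fear", "path_neutral")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$participant_id))
    stop("manifest lists a participant more than once", call. = FALSE)
  incomplete <- !nzchar(man$path_fear) | !nzchar(man$path_neutral) |
    is.na(man$path_fear) | is.na(man$path_neutral)
  if (any(incomplete))
    stop("participant(s) missing a condition file: ",
         paste(man$participant_id[incomplete], collapse = ", "), call. = FALSE)
  base <- dirname(normalizePath(path))
  for (col in c("path_fear", "path_neutral")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  man
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a full cohort of connectivity records
#'
#' Reads every participant's fear and neutral matrices listed in a manifest.
#'
#' @param manifest_path manifest CSV path (see [read_manifest()]).
#' @param node_table the \code{node_table}.
#' @param tol symmetry tolerance passed to [read_connectivity()].
#' @return list of \code{connectivity_record} (2 per participant; fear then
#'   neutral, participants in manifest order).
#' @export
load_cohort <- function(manifest_path, node_table, tol = 1e-6) {
  man <- read_manifest(manifest_path)
  if (nrow(man) == 0L) {
    warning("manifest is empty; returning no records", call. = FALSE)
    return(list())
  }
  records <- vector("list", 2L * nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    for (j in seq_along(cond <- c("fear", "neutral"))) {
      rec <- tryCatch(
        read_connectivity(row[[paste0("path_", cond[j])]], node_table, row,
                          cond[j], tol = tol),
        error = function(e)
          stop("participant ", row$participant_id, " (", cond[j], "): ",
               conditionMessage(e), call. = FALSE)
      )
      records[[2L * (i - 1L) + j]] <- rec
    }
  }
  records
}
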