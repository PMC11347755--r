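#' Validate a win-loss sociomatrix
#'
#' A sociomatrix is a square table of non-negative integer counts in which
#' entry (i, j) is the number of interactions individual i won against
#' individual j (winners in rows). The diagonal must be zero and row/column
#' identifiers must match.
#'
#' @param raw A square numeric matrix or data frame with identical row and
#'   column names (ids). If names are absent, ids `ind1..indN` are assigned.
#' @return An object of class `interaction_matrix`: the validated integer
#'   count matrix with `ids` in dimnames.
#' @examples
#' m <- validate_matrix(rbind(c(0, 3), c(1, 0)))
#' @export
validate_matrix <- function(raw) {
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) {
    stop("sociomatrix must be square: got ", nrow(m), " rows, ",
         ncol(m), " columns", call. = FALSE)
  }
  n <- nrow(m)
  if (n < 2) stop("N < 2: need at least two individuals", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("ind", seq_len(n))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  ids <- rownames(m)
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(ids, colnames(m))) {
    if (!setequal(ids, colnames(m))) {
      stop("row and column ids differ", call. = FALSE)
    }
    m <- m[, ids, drop = FALSE]  # align column order to rows
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("sociomatrix contains missing values", call. = FALSE)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative entry at cell (", ids[bad[1, 1]], ", ", ids[bad[1, 2]], ")",
         call. = FALSE)
  }
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)
    stop("non-integer count at cell (", ids[bad[1, 1]], ", ", ids[bad[1, 2]], ")",
         call. = FALSE)
  }
  dg <- which(diag(m) != 0)
  if (length(dg) > 0) {
    stop("nonzero diagonal at cell (", ids[dg[1]], ", ", ids[dg[1]], ")",
         call. = FALSE)
  }
  structure(m, class = c("interaction_matrix", "matrix"))
}

#' Read a sociomatrix from CSV
#'
#' First row and first column hold the ids; cell (i, j) is the number of wins
#' of the row individual over the column individual. Files recorded with
#' losers in rows can be transposed on read.
#'
#' @param path Path to a CSV file.
#' @param losers_in_rows If `TRUE`, transpose the table on read.
#' @return A validated `interaction_matrix`.
#' @export
read_sociomatrix <- function(path, losers_in_rows = FALSE) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                         fileEncoding = "UTF-8")
  m <- as.matrix(tab)
  if (losers_in_rows) m <- t(m)
  validate_matrix(m)
}

#' Write a sociomatrix to CSV
#' @param m An `interaction_matrix`.
#' @param path Output path.
#' @export
write_sociomatrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
}

matrix_ids <- function(m) rownames(m)
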