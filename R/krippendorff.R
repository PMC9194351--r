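#' Read a coding matrix
#'
#' Reads the CSV layout used for human-coded content: a unit id column
#' followed by one column per coder, empty cells meaning a coder did not see
#' that unit.
#'
#' @param path CSV path. The first column is taken as the unit id.
#' @return A `coding_matrix`: a units-by-coders character matrix with unit
#'   ids as row names and `NA` for missing codes.
#' @export
read_coding_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ""] <- NA_character_
  rownames(m) <- df[[1]]
  as_coding_matrix(m)
}

#' @rdname read_coding_matrix
#' @param values A units-by-coders matrix of nominal codes (`NA` = missing).
#' @export
as_coding_matrix <- function(values) {
  m <- as.matrix(values)
  mode(m) <- "character"
  if (ncol(m) < 2L) abort("a coding matrix needs at least 2 coders")
  if (!any(rowSums(!is.na(m)) >= 2L)) {
    abort("need at least one unit coded by two or more coders")
  }
  structure(m, class = c("coding_matrix", class(m)))
}

#' Krippendorff's alpha for nominal codes
#'
#' Inter-coder reliability via the coincidence-matrix formulation with the
#' nominal difference metric. Units judged by fewer than two coders carry no
#' pairing information and are dropped from the coincidence matrix. By
#' convention a matrix with zero expected disagreement (every retained code
#' identical) returns 1 with a warning, since agreement is perfect but
#' chance-corrected agreement is undefined.
#'
#' @param values A `coding_matrix` (see [as_coding_matrix()]) or any
#'   units-by-coders matrix/data frame of nominal codes with `NA` for
#'   missing.
#' @return Alpha in `[-1, 1]`; 1 is perfect agreement, 0 is chance-level.
#' @examples
#' m <- rbind(c("1", "1", "1"), c("0", "0", "0"), c("0", "1", "0"))
#' krippendorff_alpha(m)
#' @export
krippendorff_alpha <- function(values) {
  m <- as_coding_matrix(values)
  keep <- rowSums(!is.na(m)) >= 2L
  m <- m[keep, , drop = FALSE]
  codes <- sort(unique(stats::na.omit(as.vector(m))))
  k <- length(codes)
  co <- matrix(0, k, k, dimnames = list(codes, codes))
  for (u in seq_len(nrow(m))) {
    vals <- m[u, ][!is.na(m[u, ])]
    mu <- length(vals)
    idx <- match(vals, codes)
    for (a in seq_len(mu)) {
      for (b in seq_len(mu)) {
        if (a != b) co[idx[a], idx[b]] <- co[idx[a], idx[b]] + 1 / (mu - 1)
      }
    }
  }
  nc <- rowSums(co)
  n_tot <- sum(nc)
  d_o <- sum(co) - sum(diag(co))
  d_e <- (sum(nc)^2 - sum(nc^2)) / (n_tot - 1)
  if (d_e <= 0) {
    warn("zero expected disagreement; returning alpha = 1 by convention")
    return(1)
  }
  1 - d_o / d_e
}
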