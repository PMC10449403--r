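# Boundary-transformation scoring and the split-half noise ceiling.

#' Code a forced-error response as an error direction
#'
#' In the forced-error paradigm the second image is identical to the first,
#' so a "closer" judgment means the remembered view was wider than the image
#' (a boundary-extension error, coded +1) and "farther" means it was narrower
#' (a contraction error, coded -1). A memory with extended boundaries makes
#' the identical re-presentation look zoomed-in, hence the default mapping;
#' `convention = "closer_contraction"` flips it.
#'
#' @param response character vector with values `"closer"` or `"farther"`.
#' @param convention `"closer_extension"` (default) or `"closer_contraction"`.
#' @return integer vector of +1 (extension) / -1 (contraction).
#' @export
code_response <- function(response, convention = c("closer_extension",
                                                   "closer_contraction")) {
  convention <- match.arg(convention)
  bad <- !(response %in% c("closer", "farther"))
  if (any(bad)) {
    stop("unknown response label(s): ",
         paste(unique(response[bad]), collapse = ", "),
         " (expected 'closer' or 'farther')")
  }
  code <- ifelse(response == "closer", 1L, -1L)
  if (convention == "closer_contraction") code <- -code
  code
}

#' Boundary-transformation score for one image
#'
#' The mean of the +1/-1 coded errors: `(n_extension - n_contraction) /
#' n_total`, in `[-1, 1]`. Scores above 0 indicate net boundary extension,
#' below 0 net contraction.
#'
#' @param responses character vector of `"closer"`/`"farther"` responses for
#'   one image.
#' @param convention see [code_response()].
#' @return one-row data.frame: `score`, `n_extension`, `n_contraction`,
#'   `n_total`.
#' @export
score_image <- function(responses, convention = "closer_extension") {
  if (length(responses) < 1) stop("empty responses: need at least 1 response")
  code <- code_response(responses, convention)
  n_ext <- sum(code == 1L); n_con <- sum(code == -1L)
  data.frame(score = mean(code), n_extension = n_ext, n_contraction = n_con,
             n_total = n_ext + n_con)
}

#' Per-image boundary-transformation scores for a response table
#'
#' @param table data.frame with columns `participant_id`, `image_id`,
#'   `response` (one row per trial; at most one per participant x image).
#' @param convention see [code_response()].
#' @return data.frame with columns `image_id`, `score`, `n_extension`,
#'   `n_contraction`, `n_total`, one row per image.
#' @export
score_boundary <- function(table, convention = "closer_extension") {
  validate_response_table(table)
  ids <- sort(unique(as.character(table$image_id)))
  rows <- lapply(ids, function(id) {
    r <- score_image(table$response[table$image_id == id], convention)
    cbind(data.frame(image_id = id, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_response_table <- function(table) {
  need <- c("participant_id", "image_id", "response")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("response table needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(table) == 0) stop("response table is empty")
  key <- paste(table$participant_id, table$image_id)
  if (anyDuplicated(key)) {
    stop("response table has duplicate participant x image entries")
  }
  invisible(table)
}

#' Split-half noise ceiling of boundary-transformation scores
#'
#' Repeatedly bipartitions the participants at random (odd counts split
#' floor/ceiling), computes per-image scores within each half, regresses one
#' half's scores on the other's, and records the regression R-squared. The
#' returned interval is the central `interval` mass of the R-squared
#' distribution; it bounds how well any model of the per-image scores can be
#' expected to do. For this one-predictor regression, R-squared equals the
#' squared Pearson correlation of the half scores, and the implementation
#' verifies that identity on every iteration. Images missing all responses in
#' either half of an iteration are dropped from that iteration's regression.
#'
#' @param table response table (see [score_boundary()]).
#' @param n_iterations number of random splits.
#' @param interval central mass of the reported percentile interval.
#' @param seed integer seed for reproducible splits.
#' @param convention see [code_response()].
#' @return a `noise_ceiling` object: `lower`, `upper`, `n_iterations`,
#'   `interval_mass`, `seed`, and the full `r_squared` vector.
#' @export
noise_ceiling <- function(table, n_iterations = 10000, interval = 0.95,
                          seed = 1, convention = "closer_extension") {
  validate_response_table(table)
  parts <- sort(unique(as.character(table$participant_id)))
  imgs <- sort(unique(as.character(table$image_id)))
  if (length(parts) < 4) stop("insufficient data: need >= 4 participants")
  if (length(imgs) < 3) stop("insufficient data: need >= 3 images")
  code <- code_response(as.character(table$response), convention)
  m <- matrix(NA_real_, length(parts), length(imgs),
              dimnames = list(parts, imgs))
  m[cbind(match(as.character(table$participant_id), parts),
          match(as.character(table$image_id), imgs))] <- code
  np <- length(parts)
  half <- floor(np / 2)
  set.seed(seed)
  r2 <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    perm <- sample.int(np)
    a <- colMeans(m[perm[seq_len(half)], , drop = FALSE], na.rm = TRUE)
    b <- colMeans(m[perm[(half + 1):np], , drop = FALSE], na.rm = TRUE)
    keep <- is.finite(a) & is.finite(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 3 || stats::var(b) == 0 || stats::var(a) == 0) {
      r2[it] <- NA_real_
      next
    }
    slope <- stats::cov(a, b) / stats::var(b)
    res <- a - (mean(a) - slope * mean(b)) - slope * b
    r2v <- 1 - sum(res^2) / sum((a - mean(a))^2)
    stopifnot(abs(r2v - stats::cor(a, b)^2) < 1e-9) # internal identity check
    r2[it] <- r2v
  }
  r2 <- r2[is.finite(r2)]
  if (length(r2) == 0) stop("insufficient data: no split produced a regression")
  alpha <- (1 - interval) / 2
  qs <- stats::quantile(r2, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(lower = qs[1], upper = qs[2], n_iterations = n_iterations,
                 interval_mass = interval, seed = seed, r_squared = r2),
            class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("<noise_ceiling> %d%% of %d splits: R^2 in [%.3f, %.3f]\n",
              round(100 * x$interval_mass), x$n_iterations, x$lower, x$upper))
  invisible(x)
}

#' Read a response table CSV
#'
#' @param path CSV with columns `participant_id,image_id,response`.
#' @return validated response data.frame.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("responses file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_response_table(tab)
  tab
}
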