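# Contrast codes for the four fixed factors.
#
# Missing beats (levels 0..3) uses a simple contrast (level 0 against the
# mean of levels 1..3) plus orthogonal linear and quadratic polynomials
# over levels 1..3 only, so that the strictly-metric level does not enter
# the polynomial trend.  Off-beat category (few/some/many) uses
# orthogonal linear and quadratic polynomials.  Accent type is sum-coded
# (temporal = +1, intensity = -1).  Musical training enters as a centred
# continuous covariate.

mb_codes <- function(mb) {
  mb <- as.integer(mb)
  stopifnot(all(mb %in% 0:3))
  cbind(
    mb_simple = ifelse(mb == 0L, -0.75, 0.25),
    mb_lin    = c(0, -1, 0, 1)[mb + 1L] / sqrt(2),
    mb_quad   = c(0, 1, -2, 1)[mb + 1L] / sqrt(6)
  )
}

ob_codes <- function(category) {
  lev <- match(category, c("few", "some", "many"))
  if (anyNA(lev)) stop("off-beat category must be few/some/many")
  cbind(
    ob_lin  = c(-1, 0, 1)[lev] / sqrt(2),
    ob_quad = c(1, -2, 1)[lev] / sqrt(6)
  )
}

type_codes <- function(accent_type) {
  v <- ifelse(accent_type == "temporal", 1,
              ifelse(accent_type == "intensity", -1, NA))
  if (anyNA(v)) stop("accent_type must be temporal or intensity")
  cbind(type = v)
}

#' Contrast scheme and full-interaction design matrix
#'
#' Expands rating records onto the contrast basis of the difficulty
#' model: 7 main-effect columns (3 missing-beats, 2 off-beat, 1 type,
#' 1 training) and every interaction up to the four-way product, 47
#' candidate columns in all.  Because the published condition structure
#' is not factorial (zero missing beats occurs only with few off-beat
#' accents), some interaction columns are linear combinations of
#' lower-order ones; these are removed by a greedy rank-revealing sweep
#' that always prefers lower-order terms, and the per-term retained
#' degrees of freedom are reported.
#'
#' @param records Data frame with columns `missing_beats`,
#'   `off_beat_category` (or `category`), `accent_type`,
#'   `training_years`.
#' @param terms Character vector of term labels to include (default all
#'   15).  Labels combine `"missing"`, `"offbeat"`, `"type"`,
#'   `"training"` with `:`.
#' @param center_training Value used to centre training years; defaults
#'   to the sample mean.
#' @param tol Relative tolerance of the rank test.
#' @return List of class `"clmm_design"`: `X` (retained columns),
#'   `term` (term label per retained column), `dropped` (names of
#'   aliased columns), `term_df` (named vector), `center_training`.
#' @export
build_design <- function(records, terms = design_terms(),
                         center_training = NULL, tol = 1e-8) {
  if (length(terms) == 0L) {
    return(structure(list(
      X = matrix(numeric(0), nrow = nrow(records), ncol = 0L,
                 dimnames = list(NULL, character(0))),
      term = character(0), dropped = character(0),
      term_df = stats::setNames(integer(0), character(0)),
      center_training = if ("training_years" %in% names(records))
        mean(records$training_years) else 0,
      range_training = if ("training_years" %in% names(records))
        range(records$training_years) else c(0, 0),
      terms = character(0)), class = "clmm_design"))
  }
  cat_col <- if ("off_beat_category" %in% names(records))
    records$off_beat_category else records$category
  blocks <- list(
    missing = mb_codes(records$missing_beats),
    offbeat = ob_codes(cat_col),
    type    = type_codes(records$accent_type)
  )
  if (is.null(center_training))
    center_training <- mean(records$training_years)
  blocks$training <- cbind(training = records$training_years -
                             center_training)
  for (b in names(blocks)) {
    if (nrow(unique(blocks[[b]])) < 2L)
      stop(sprintf("factor '%s' has a single observed level", b))
  }
  terms <- match.arg(terms, design_terms(), several.ok = TRUE)
  cols <- list(); labs <- character(0)
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    m <- blocks[[parts[1L]]]
    if (length(parts) > 1L) for (p in parts[-1L]) {
      m2 <- blocks[[p]]
      m <- do.call(cbind, lapply(seq_len(ncol(m2)), function(j) {
        out <- m * m2[, j]
        colnames(out) <- paste(colnames(m), colnames(m2)[j], sep = ":")
        out
      }))
    }
    cols[[tm]] <- m
    labs <- c(labs, rep(tm, ncol(m)))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(lapply(cols, colnames))
  keep <- rank_retain(X, tol = tol)
  term_df <- vapply(terms, function(tm) sum(keep & labs == tm), 0L)
  structure(list(X = X[, keep, drop = FALSE],
                 term = labs[keep],
                 dropped = colnames(X)[!keep],
                 term_df = term_df,
                 center_training = center_training,
                 range_training = range(records$training_years),
                 terms = terms),
            class = "clmm_design")
}

#' @rdname build_design
#' @export
design_terms <- function() {
  main <- c("missing", "offbeat", "type", "training")
  two <- utils::combn(main, 2L, paste, collapse = ":")
  three <- utils::combn(main, 3L, paste, collapse = ":")
  c(main, two, three, paste(main, collapse = ":"))
}

# Greedy rank-revealing column selection: iterate columns in order,
# keeping a column when it is not (numerically) in the span of the
# intercept plus the columns already kept.  Gram-Schmidt against an
# orthonormal basis.
rank_retain <- function(X, tol = 1e-8) {
  n <- nrow(X)
  basis <- matrix(rep(1 / sqrt(n), n), ncol = 1L)  # intercept direction
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    nv <- sqrt(sum(v^2))
    if (nv < tol) next
    r <- v - basis %*% crossprod(basis, v)
    r <- r - basis %*% crossprod(basis, r)   # reorthogonalise once
    if (sqrt(sum(r^2)) > tol * nv) {
      keep[j] <- TRUE
      basis <- cbind(basis, r / sqrt(sum(r^2)))
    }
  }
  keep
}
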