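# Error-validation machinery: sample-size formula, Wilson score interval,
# seeded sampling plans for analogue/digital sources, cross-confirmation
# pre-filter.

#' Required random-sample size for estimating an error rate
#'
#' Computes `n = z^2 p (1 - p) / e^2`, rounded up (ceiling), for a binomial
#' error-rate estimate at confidence quantile `z`, margin of error `e` and
#' assumed error rate `p`. At the defaults (95% confidence, 1% margin, 7%
#' assumed error rate) this gives n = 2501.
#'
#' @param z Standard-normal quantile (> 0), e.g. 1.96 for 95% confidence.
#' @param e Margin of error, a proportion in (0, 1).
#' @param p Assumed error rate, a proportion in \[0, 1\].
#' @return Integer sample size.
#' @export
#' @examples
#' required_sample_size(1.96, 0.01, 0.07)
required_sample_size <- function(z = 1.96, e = 0.01, p = 0.07) {
  stopifnot(is.numeric(z), is.numeric(e), is.numeric(p), z > 0,
            p >= 0, p <= 1)
  if (e <= 0 || e >= 1) stop("Margin of error must be in (0, 1)",
                             call. = FALSE)
  as.integer(ceiling(z^2 * p * (1 - p) / e^2))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score-test inversion interval; better behaved than the Wald interval
#' for proportions near zero, as with low observed error counts.
#'
#' @param errors Number of observed errors (successes), `0 <= errors <= n`.
#' @param n Sample size (> 0).
#' @param z Standard-normal quantile (default 1.96 for a 95% interval).
#' @return A one-row tibble with `estimate` (`errors/n`), `lower`, `upper`.
#' @export
#' @examples
#' wilson_interval(3, 2501)
wilson_interval <- function(errors, n, z = 1.96) {
  stopifnot(length(errors) == 1L, length(n) == 1L, z > 0)
  if (n <= 0) stop("Sample size must be positive", call. = FALSE)
  if (errors < 0 || errors > n) {
    stop("errors must lie in [0, n]", call. = FALSE)
  }
  phat <- errors / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  tibble::tibble(estimate = phat,
                 lower = max(0, centre - half),
                 upper = min(1, centre + half))
}

#' Round half-up to a number of decimals
#'
#' Used when echoing interval endpoints at printed precision (R's `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Draw the error-validation sample of records
#'
#' Digital sources were extracted by scripts, so their error is checked with
#' a small fixed number of records per source: `per_digital` records (or all
#' if the source has fewer) are drawn per digital citation. Records from
#' analogue sources (manually transcribed) form one pool from which
#' `n_analogue` records are drawn uniformly without replacement (or all if
#' fewer). Sampling is reproducible under `seed`.
#'
#' @param records Interaction tibble; every citation must resolve in `refs`.
#' @param refs Reference meta-dataset (see [as_references()]) with
#'   `Data_Type` `Digital`/`Analogue` per citation.
#' @param n_analogue Analogue sample size, e.g. [required_sample_size()].
#' @param per_digital Records to check per digital source (default 5).
#' @param seed Optional integer seed.
#' @return A tibble of sampled records with extra columns `Sample_Stratum`
#'   (`"analogue"`/`"digital"`) and `Sampled_Source` (the digital citation
#'   ID, `NA` for the analogue pool).
#' @export
build_validation_sample <- function(records, refs, n_analogue,
                                    per_digital = 5L, seed = NULL) {
  records <- tibble::as_tibble(records)
  refs <- as_references(refs)
  cited <- unique(unlist(records$Citation))
  unresolved <- setdiff(cited, refs$Citation)
  if (length(unresolved) > 0L) {
    stop("Citation ID(s) not in reference table: ",
         paste(head(unresolved, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  type_of <- setNames(refs$Data_Type, refs$Citation)
  has_analogue <- purrr::map_lgl(records$Citation, function(cc) {
    any(type_of[as.character(cc)] == "Analogue")
  })
  analogue_pool <- which(has_analogue)
  n_a <- min(n_analogue, length(analogue_pool))
  a_idx <- if (n_a > 0L) sort(sample(analogue_pool, n_a)) else integer(0)
  analogue <- records[a_idx, , drop = FALSE]
  if (nrow(analogue) > 0L) {
    analogue$Sample_Stratum <- "analogue"
    analogue$Sampled_Source <- NA_integer_
  }
  digital_ids <- refs$Citation[refs$Data_Type == "Digital"]
  digital <- purrr::map_dfr(digital_ids, function(cid) {
    pool <- which(purrr::map_lgl(records$Citation, ~ cid %in% .x))
    if (length(pool) == 0L) return(NULL)
    take <- sort(sample(pool, min(per_digital, length(pool))))
    out <- records[take, , drop = FALSE]
    out$Sample_Stratum <- "digital"
    out$Sampled_Source <- cid
    out
  })
  dplyr::bind_rows(analogue, digital)
}

#' Split a validation sample by cross-confirmation
#'
#' A sampled record whose (consumer, resource) pair is documented by at
#' least two distinct sources in the metaweb is assumed correct (confirmed
#' by an independent source); the rest require a manual check against their
#' source.
#'
#' @param sample Tibble of sampled records (must carry `Source_Name`,
#'   `Target_Name`).
#' @param web A [metaweb()] whose merged citation sets decide confirmation.
#' @return A list with `auto_confirmed` and `needs_manual_check` tibbles.
#' @export
cross_confirmation_filter <- function(sample, web) {
  validate_metaweb(web)
  sample <- tibble::as_tibble(sample)
  ints <- web$interactions
  key_web <- paste(ints$Source_Name, ints$Target_Name, sep = "\r")
  n_cites <- setNames(lengths(ints$Citation), key_web)
  key <- paste(sample$Source_Name, sample$Target_Name, sep = "\r")
  n <- n_cites[key]
  n[is.na(n)] <- 0L
  confirmed <- n >= 2L
  list(auto_confirmed = sample[confirmed, , drop = FALSE],
       needs_manual_check = sample[!confirmed, , drop = FALSE])
}
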