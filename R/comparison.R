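# Cross-metaweb comparison: per-web degree summaries and residual-based
# outlier detection against species richness with a network-type grouping.

#' Total-degree summary of a metaweb
#'
#' Total degree of a node is its in-degree plus out-degree over the unique
#' links of the web (a self-loop contributes one to each). Isolated
#' checklist taxa count with degree zero.
#'
#' @param web A [metaweb()] with at least one taxon.
#' @return A one-row tibble: `mean_total_degree`, `sd_total_degree`
#'   (sample SD), `richness` (node count).
#' @export
degree_summaries <- function(web) {
  validate_metaweb(web)
  if (nrow(web$taxa) == 0L) stop("Empty web", call. = FALSE)
  deg <- total_degrees(web)$total_degree
  tibble::tibble(mean_total_degree = mean(deg),
                 sd_total_degree = stats::sd(deg),
                 richness = nrow(web$taxa))
}

#' Per-taxon total degrees
#'
#' @param web A [metaweb()].
#' @return A tibble `(taxon, in_degree, out_degree, total_degree)` covering
#'   every checklist taxon.
#' @export
total_degrees <- function(web) {
  validate_metaweb(web)
  ints <- web$interactions
  out_d <- table(factor(ints$Source_Name, levels = web$taxa$Taxon))
  in_d <- table(factor(ints$Target_Name, levels = web$taxa$Taxon))
  tibble::tibble(taxon = web$taxa$Taxon,
                 in_degree = as.integer(in_d),
                 out_degree = as.integer(out_d),
                 total_degree = as.integer(in_d + out_d))
}

fit_metric_residuals <- function(data, metric, method, log_richness) {
  data$.y <- data[[metric]]
  data$.x <- if (log_richness) log10(data$Richness) else data$Richness
  if (stats::sd(data$.x) == 0) {
    stop("Degenerate fit: all webs have the same richness", call. = FALSE)
  }
  n_types <- dplyr::n_distinct(data$Network_Type)
  res <- NULL
  if (method == "mixed" && n_types >= 2L) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(.y ~ .x + (1 | Network_Type), data = data)
      )),
      error = function(e) NULL)
    if (!is.null(fit)) res <- stats::residuals(fit)
  }
  if (is.null(res)) {
    # fixed-effect fallback: per-group intercepts
    fml <- if (n_types >= 2L) .y ~ .x + Network_Type else .y ~ .x
    res <- stats::residuals(stats::lm(fml, data = data))
  }
  unname(res)
}

#' Residual-based outlier analysis across metaweb summaries
#'
#' Models each degree metric (mean total degree, and separately its SD)
#' against species richness (log10 by default) with the network type
#' (bitrophic vs multitrophic) as a grouping effect, then flags webs whose
#' residual lies outside `mean(residuals) +/- sigma_mult * sd(residuals)`.
#' The grouping effect is fitted as a random intercept via [lme4::lmer()]
#' (`method = "mixed"`); `method = "fixed"` uses per-group fixed intercepts
#' in an ordinary linear model, the documented fallback that the outlier
#' decision must be robust to. With a single network type both reduce to a
#' simple regression.
#'
#' @param summaries Metaweb summary table (see [as_metaweb_summaries()]);
#'   at least 3 rows.
#' @param focal Optional name of the focal web to report a flag for.
#' @param sigma_mult Outlier threshold in residual standard deviations
#'   (default 2).
#' @param method `"mixed"` or `"fixed"` (see above).
#' @param log_richness Model against log10 richness (default) or raw
#'   richness.
#' @return An object of class `metaweb_comparison`: list with `results`
#'   (tibble: `Name`, `Network_Type`, `Richness`, `metric`, `residual`,
#'   `z`, `outlier`), `focal`, `focal_flagged` (named logical per metric),
#'   `sigma_mult`, `method`.
#' @export
residual_outlier_analysis <- function(summaries, focal = NULL,
                                      sigma_mult = 2,
                                      method = c("mixed", "fixed"),
                                      log_richness = TRUE) {
  method <- match.arg(method)
  data <- as_metaweb_summaries(summaries)
  if (nrow(data) < 3L) {
    stop("Need at least 3 metaweb summaries", call. = FALSE)
  }
  if (!is.null(focal) && !focal %in% data$Name) {
    stop("Focal web '", focal, "' not in the summary table", call. = FALSE)
  }
  metrics <- c("Mean_Total_Degree", "SD_Total_Degree")
  results <- purrr::map_dfr(metrics, function(m) {
    res <- fit_metric_residuals(data, m, method, log_richness)
    s <- stats::sd(res)
    # an (effectively) exact fit has no outliers: do not standardise
    # floating-point noise into z-scores
    tol <- 1e-8 * max(1, stats::sd(data[[m]]))
    z <- if (s < tol) rep(0, length(res)) else (res - mean(res)) / s
    tibble::tibble(Name = data$Name, Network_Type = data$Network_Type,
                   Richness = data$Richness, metric = m, residual = res,
                   z = z, outlier = abs(z) > sigma_mult)
  })
  focal_flagged <- if (is.null(focal)) NULL else {
    f <- results[results$Name == focal, , drop = FALSE]
    setNames(f$outlier, f$metric)
  }
  structure(list(results = results, focal = focal,
                 focal_flagged = focal_flagged, sigma_mult = sigma_mult,
                 method = method, log_richness = log_richness),
            class = "metaweb_comparison")
}

#' @export
print.metaweb_comparison <- function(x, ...) {
  n_out <- sum(x$results$outlier)
  cat("<metaweb_comparison> ", dplyr::n_distinct(x$results$Name), " webs, ",
      n_out, " outlier flag(s) at ", x$sigma_mult, " sigma (method: ",
      x$method, ")\n", sep = "")
  if (!is.null(x$focal)) {
    cat("focal '", x$focal, "' flagged: ",
        paste(names(x$focal_flagged), unname(x$focal_flagged),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.metaweb_comparison <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.metaweb_comparison <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$metric),
    n_webs = dplyr::n(),
    sd_residual = stats::sd(.data$residual),
    n_outliers = sum(.data$outlier),
    .groups = "drop"
  )
}

#' Plot residuals against richness with sigma bands
#'
#' Mirrors the standard residual-comparison figure: one panel per degree
#' metric, residual against log10 richness, shaded one- and two-sigma bands
#' around the mean residual, point shape by network type, outliers labelled.
#'
#' @param object A `metaweb_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metaweb_comparison <- function(object, ...) {
  d <- object$results
  bands <- dplyr::summarise(
    dplyr::group_by(d, .data$metric),
    m = mean(.data$residual), s = stats::sd(.data$residual),
    .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$Richness),
                                  y = .data$residual)) +
    ggplot2::geom_rect(data = bands, inherit.aes = FALSE,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = .data$m - 2 * .data$s,
                                    ymax = .data$m + 2 * .data$s),
                       fill = "wheat", alpha = 0.4) +
    ggplot2::geom_rect(data = bands, inherit.aes = FALSE,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = .data$m - .data$s,
                                    ymax = .data$m + .data$s),
                       fill = "wheat3", alpha = 0.4) +
    ggplot2::geom_hline(data = bands,
                        ggplot2::aes(yintercept = .data$m),
                        linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$Network_Type,
                                     colour = .data$outlier), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "log10 species richness", y = "residual",
                  shape = "network type", colour = "outlier") +
    ggplot2::theme_minimal()
}

#' Degree-distribution plot for a metaweb
#'
#' @param web A [metaweb()].
#' @return A ggplot histogram of per-taxon total degree.
#' @export
plot_degree_distribution <- function(web) {
  d <- total_degrees(web)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "total degree (in + out)", y = "taxa") +
    ggplot2::theme_minimal()
}
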