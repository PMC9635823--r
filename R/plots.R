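#' Plot an MDS embedding
#'
#' @param object A `pk_mds` from [classical_mds()].
#' @param groups Optional named vector id -> group used for colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_mds <- function(object, groups = NULL, ...) {
  df <- tidy.pk_mds(object)
  df$group <- if (is.null(groups)) "all" else unname(groups[df$id])
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL,
                  title = "MDS of (1 - f3) dissimilarities") +
    ggplot2::theme_minimal()
}

#' Plot an isolation-by-distance fit
#'
#' @param object A `pk_ibd` from [ibd_regression()].
#' @param ... Unused.
#' @return A ggplot of genetic vs geographic distance with the OLS line.
#' @export
autoplot.pk_ibd <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$dist_km, .data$dist_gen)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.7) +
    ggplot2::labs(x = "geographic distance (km)", y = "genetic distance (1 - f3)") +
    ggplot2::theme_minimal()
}

#' Plot admixture weights with standard errors
#'
#' @param object A `pk_qpadm` from [fit_admixture()].
#' @param ... Unused.
#' @return A ggplot bar chart of source weights +/- 1 SE.
#' @export
autoplot.pk_qpadm <- function(object, ...) {
  df <- tidy.pk_qpadm(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$estimate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                        ymax = .data$estimate + .data$std.error),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "admixture weight",
                  title = paste0(object$target, " (p = ",
                                 format(object$p, digits = 2), ")")) +
    ggplot2::theme_minimal()
}

#' Plot pairwise kinship estimates against the degree expectations
#'
#' @param object A `pk_kinship` from [kinship_read()].
#' @param ... Unused.
#' @return A ggplot of normalized P0 per pair with classification bands.
#' @export
autoplot.pk_kinship <- function(object, ...) {
  df <- as_tibble(object)
  df$pair <- paste(df$id1, df$id2, sep = "-")
  df <- df[order(df$normalized), ]
  df$rank <- seq_len(nrow(df))
  expect <- tibble(level = c("identical", "first", "second", "third", "unrelated"),
                   value = c(0.5, 0.75, 0.875, 0.9375, 1))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$normalized)) +
    ggplot2::geom_hline(data = expect,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$normalized - 2 * .data$se,
                                          ymax = .data$normalized + 2 * .data$se,
                                          colour = .data$degree)) +
    ggplot2::labs(x = "pair (ranked)", y = "normalized P0", colour = "degree") +
    ggplot2::theme_minimal()
}

#' Plot stacked summed probability distributions of calibrated dates
#'
#' @param spd Output of [spd_stack()].
#' @return A ggplot with one panel-free line per group; the x axis runs
#'   back in time (cal BCE).
#' @export
plot_spd <- function(spd) {
  ggplot2::ggplot(spd, ggplot2::aes(.data$bin_start, .data$mass,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5,
                      width = min(diff(sort(unique(spd$bin_start))), 100)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "year (cal BCE)", y = "summed probability", fill = NULL) +
    ggplot2::theme_minimal()
}
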