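#' Basic figures for the two-environment comparison
#'
#' Thin ggplot2 wrappers around [manhattan_table()] and [quadrant_table()].
#' ggplot2 is only suggested; the data tables are the primary interface.
#'
#' @param effects a `snp_effect_table` with percentage columns.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(effects) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_manhattan() needs the ggplot2 package", call. = FALSE)
  }
  tab <- manhattan_table(effects)
  ggplot2::ggplot(tab, ggplot2::aes(x = cum_pos, y = pct_var,
                                    colour = chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~env, ncol = 1) +
    ggplot2::labs(x = "cumulative position (bp)",
                  y = "explained additive variance (%)")
}

#' @rdname plot_manhattan
#' @param cmp a `topk_comparison` from [top_k()].
#' @export
plot_quadrants <- function(cmp) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_quadrants() needs the ggplot2 package", call. = FALSE)
  }
  tab <- quadrant_table(cmp)
  ggplot2::ggplot(tab, ggplot2::aes(x = pct_env1, y = pct_env2,
                                    colour = quadrant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = cmp$T_env1, linetype = 2) +
    ggplot2::geom_hline(yintercept = cmp$T_env2, linetype = 2) +
    ggplot2::labs(
      x = sprintf("%% variance, %s", cmp$envs[1]),
      y = sprintf("%% variance, %s", cmp$envs[2])
    )
}
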