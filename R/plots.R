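# ggplot2 views of the result types.

#' Per-residue B-factor profile plot
#'
#' @param structure a `pdb_structure`.
#' @param policy per-residue reduction (`"mean"` or `"ca"`).
#' @return a ggplot object.
#' @export
plot_bfactor_profile <- function(structure, policy = "mean") {
  pb <- per_residue_bfactor(structure, policy)
  ggplot2::ggplot(pb, ggplot2::aes(x = .data$res_seq, y = .data$b_factor)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "Residue", y = expression(B-factor ~ (ring(A)^2)))
}

#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$res_seq, y = .data$rmsf)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "Residue", y = expression(RMSF ~ (ring(A))))
}

#' @export
autoplot.dccm_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("residue_i", "residue_j", "correlation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_i, y = .data$residue_j,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "C_ij") +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(s = seq(min(object$data$s), max(object$data$s),
                         length.out = 100))
  grid$v <- object$vmax * grid$s / (object$km + grid$s)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$s, y = .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::labs(x = "Substrate (mg/mL)", y = "Velocity")
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble(t = seq(min(object$data$t), max(object$data$t),
                         length.out = 100))
  grid$a <- object$a0 * exp(-object$k * grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$a)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = "Residual activity")
}
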