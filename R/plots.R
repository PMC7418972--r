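#' @method autoplot masked_image
#' @export
autoplot.masked_image <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$pixels)),
                    col = seq_len(ncol(object$pixels)))
  df$intensity <- as.vector(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s / %s", object$subject_id,
                                  object$scanner_id)) +
    ggplot2::theme_void()
}
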