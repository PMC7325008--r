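#' Plot recognition metrics against message length
#'
#' One panel per metric, message length K on the x axis, one curve per
#' channel (and per encoder if several are bound together).
#'
#' @param object A `ctor_experiment` tibble from
#'   [run_recognition_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctor_experiment
#' @export
autoplot.ctor_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("bcr", "scr", "ccr", "accr"),
    names_to = "metric", values_to = "rate"
  ) |>
    dplyr::mutate(metric = factor(
      toupper(.data$metric), levels = c("BCR", "SCR", "CCR", "ACCR")
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$K, y = .data$rate,
    colour = .data$channel, linetype = .data$encoder
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(
      x = "message length K (bits)", y = "rate",
      colour = "channel", linetype = "encoder"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an MLE-versus-MAP run
#'
#' @param object A `ctor_map_mle` from [run_map_vs_mle()].
#' @param type `"trace"` (per-iteration BCR by scheme), `"kymograph"`
#'   (per-bit correctness across iterations) or `"priors"` (MAP prior on
#'   each valid transition across iterations).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctor_map_mle
#' @export
autoplot.ctor_map_mle <- function(object,
                                  type = c("trace", "kymograph", "priors"),
                                  ...) {
  type <- match.arg(type)
  if (type == "trace") {
    return(
      ggplot2::ggplot(object$iterations, ggplot2::aes(
        x = .data$iteration, y = .data$bcr, colour = .data$scheme
      )) +
        ggplot2::geom_line(alpha = 0.7) +
        ggplot2::labs(x = "iteration", y = "bit correct rate") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "kymograph") {
    long <- purrr::imap(object$bit_correct, function(mat, scheme) {
      tibble::tibble(
        scheme = scheme,
        iteration = rep(seq_len(nrow(mat)), ncol(mat)),
        bit = rep(seq_len(ncol(mat)), each = nrow(mat)),
        correct = as.vector(mat)
      )
    }) |> purrr::list_rbind()
    return(
      ggplot2::ggplot(long, ggplot2::aes(
        x = .data$bit, y = .data$iteration, fill = .data$correct
      )) +
        ggplot2::geom_raster() +
        ggplot2::facet_wrap(ggplot2::vars(.data$scheme)) +
        ggplot2::scale_fill_manual(
          values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac")
        ) +
        ggplot2::labs(x = "bit position", y = "iteration",
                      fill = "decoded correctly") +
        ggplot2::theme_minimal()
    )
  }
  pr <- dplyr::mutate(
    object$priors_trace,
    transition = paste0("S", .data$from, "→S", .data$to)
  )
  ggplot2::ggplot(pr, ggplot2::aes(
    x = .data$iteration, y = .data$transition, fill = .data$prior
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "iteration", y = "state transition",
                  fill = "prior") +
    ggplot2::theme_minimal()
}
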