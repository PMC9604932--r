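#' Plot an ECG record
#'
#' Faceted lead-by-lead trace of the record.
#'
#' @param object an [ecg_record()].
#' @param leads leads to show (default all).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, leads = object$lead_names, ...) {
  df <- as_tibble.ecg_record(object)
  df <- tidyr::pivot_longer(df, -"time", names_to = "lead",
                            values_to = "mV")
  df <- dplyr::filter(df, .data$lead %in% leads)
  df$lead <- factor(df$lead, levels = object$lead_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "mV")
}

#' Plot an averaged beat template
#'
#' @param object a [beat_template()].
#' @param leads leads to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.beat_template <- function(object, leads = rownames(object$samples),
                                   ...) {
  rec <- ecg_record(object$samples, fs = object$fs)
  p <- autoplot.ecg_record(rec, leads = leads) +
    ggplot2::geom_vline(xintercept = (object$r_index - 1) / object$fs,
                        linetype = "dashed", colour = "grey50")
  p
}

#' Plot a P-wave isolation result
#'
#' Overlays the isolated P wave, the QRS component and the remainder for
#' one lead.
#'
#' @param object a `p_isolation` from [isolate_p_wave()].
#' @param lead lead name (default "II").
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.p_isolation <- function(object, lead = "II", ...) {
  t <- (seq_len(ncol(object$p_wave)) - 1) / object$fs
  df <- tibble::tibble(
    time = rep(t, 3),
    mV = c(object$p_wave[lead, ], object$qrs[lead, ],
           object$remainder[lead, ]),
    component = rep(c("P wave", "QRS", "remainder"), each = length(t)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mV,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mV", title = paste("lead", lead))
}

#' Plot the P-loop in the PC1-PC2 plane
#'
#' @param ploop a [pca_ploop()] result.
#' @return A ggplot object.
#' @export
plot_p_loop <- function(ploop) {
  df <- tibble::tibble(PC1 = ploop$pc_series[1, ], PC2 = ploop$pc_series[2, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "P-loop (PC1 vs PC2)")
}

#' ROC curves of a study's fitted models
#'
#' @param object an `af_study` from [run_study()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.af_study <- function(object, ...) {
  te <- object$data$set == "test"
  y <- as.integer(object$data$label[te])
  dfs <- purrr::imap(object$models, function(m, nm) {
    X <- as.matrix(object$data[te, m$features])
    sc <- score_model(m, X)
    th <- sort(unique(sc), decreasing = TRUE)
    tibble::tibble(
      model = nm,
      fpr = vapply(th, function(t) mean(sc[y == 0] >= t), numeric(1)),
      tpr = vapply(th, function(t) mean(sc[y == 1] >= t), numeric(1)))
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
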