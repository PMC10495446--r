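# Per-recording HTML report: global spectrum with band shading and APF
# markers, per-band source-power table, connectivity heatmaps, graph
# summaries and preprocessing counts. Figures are embedded as base64 PNG
# data URIs so the report is a single self-contained file.

#' ggplot of a global power spectrum with band shading and APF markers
#'
#' @param ps a `power_spectrum`
#' @param bands named band list
#' @param apf optional list with `peak_maximum_hz`, `cog_hz`
#' @return a ggplot object
#' @export
plot_spectrum <- function(ps, bands = default_params()$bands, apf = NULL) {
  df <- data.frame(freq = ps$freq, power = ps$global)
  ylim <- range(ps$global[ps$global > 0])
  bdf <- data.frame(band = names(bands),
                    lo = vapply(bands, `[`, 0, 1),
                    hi = vapply(bands, `[`, 0, 2),
                    ymin = ylim[1], ymax = ylim[2])
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_rect(data = bdf, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$band),
                       alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(paste("Power (", mu, V^2, "/Hz)")),
                  fill = "Band") +
    ggplot2::theme_minimal()
  if (!is.null(apf)) {
    if (!is.na(apf$peak_maximum_hz %||% NA))
      gg <- gg + ggplot2::geom_vline(xintercept = apf$peak_maximum_hz,
                                     linetype = 2, color = "red")
    if (!is.na(apf$cog_hz %||% NA))
      gg <- gg + ggplot2::geom_vline(xintercept = apf$cog_hz,
                                     linetype = 3, color = "blue")
  }
  gg
}

#' ggplot heatmap of a connectivity matrix
#' @param cm a `connectivity_matrix`
#' @return a ggplot object
#' @export
plot_connectivity <- function(cm) {
  m <- cm$matrix
  df <- expand.grid(a = seq_len(nrow(m)), b = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s %.1f-%.1f Hz", cm$measure, cm$band[1], cm$band[2]),
                  x = "ROI", y = "ROI", fill = cm$measure) +
    ggplot2::theme_minimal()
}

png_data_uri <- function(plot, width = 900, height = 450) {
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp, width = width, height = height, res = 110)
  print(plot)
  grDevices::dev.off()
  uri <- paste0("data:image/png;base64,",
                jsonlite::base64_enc(readBin(tmp, "raw", file.info(tmp)$size)))
  unlink(tmp)
  uri
}

html_table <- function(df) {
  hd <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""), "</tr>")
  rows <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table border='1' cellpadding='4' style='border-collapse:collapse'>",
         hd, paste(rows, collapse = ""), "</table>")
}

#' Render a per-recording HTML report
#'
#' @param bundle a `feature_bundle`
#' @param runlog run log (defaults to the one embedded in the bundle)
#' @param out_html output path
#' @return invisibly, `out_html`
#' @export
render_report <- function(bundle, runlog = bundle$runlog, out_html) {
  apf_txt <- if (is.na(bundle$apf$peak_maximum_hz))
    "peak: none" else sprintf("peak: %.2f Hz", bundle$apf$peak_maximum_hz)
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>resteeg report sub-%s</title></head><body>", bundle$subject),
    sprintf("<h1>Recording report: sub-%s</h1>", bundle$subject),
    "<h2>Preprocessing</h2>")
  if (!is.null(runlog)) {
    parts <- c(parts, html_table(data.frame(
      quantity = c("Rejected channels", "Rejected ICs", "Bad segments (s)",
                   "Epochs kept", "Duration in (s)"),
      value = c(sprintf("%d (%.0f%%)", runlog$n_rejected_channels,
                        100 * runlog$frac_rejected_channels),
                runlog$n_removed_ics,
                sprintf("%.1f (%.0f%%)", runlog$bad_segment_s,
                        100 * runlog$frac_bad_segments),
                runlog$n_epochs, runlog$duration_in_s))))
  }
  parts <- c(parts,
    "<h2>Global power spectrum</h2>",
    sprintf("<p>Alpha peak frequency: %s; center of gravity: %.2f Hz</p>",
            apf_txt, bundle$apf$cog_hz),
    sprintf("<img src='%s' alt='global power spectrum'/>",
            png_data_uri(plot_spectrum(bundle$spectrum, bundle$params$bands, bundle$apf))))
  if (length(bundle$source_power)) {
    sp <- do.call(cbind, lapply(bundle$source_power, function(v)
      signif(utils::head(sort(v, decreasing = TRUE), 5), 3)))
    parts <- c(parts, "<h2>Source power (top 5 ROIs per band)</h2>",
               html_table(data.frame(rank = 1:5, sp, check.names = FALSE)))
  }
  if (length(bundle$connectivity)) {
    parts <- c(parts, "<h2>Connectivity</h2>")
    for (nm in names(bundle$connectivity))
      parts <- c(parts, sprintf("<img src='%s' alt='connectivity %s' width='420'/>",
                                png_data_uri(plot_connectivity(bundle$connectivity[[nm]]),
                                             width = 450, height = 400), nm))
  }
  if (length(bundle$graphs)) {
    gdf <- do.call(rbind, lapply(names(bundle$graphs), function(nm) {
      g <- bundle$graphs[[nm]]$global
      data.frame(feature = nm,
                 clustering = signif(g$global_clustering, 3),
                 efficiency = signif(g$global_efficiency, 3),
                 smallworldness = signif(g$smallworldness, 3))
    }))
    parts <- c(parts, "<h2>Graph metrics</h2>", html_table(gdf))
  }
  parts <- c(parts, sprintf("<hr/><p><small>resteeg %s, %s</small></p>",
                            bundle$provenance$package_version,
                            bundle$provenance$created),
             "</body></html>")
  writeLines(parts, out_html)
  invisible(out_html)
}
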