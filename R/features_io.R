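# Feature bundle: the per-recording outputs of the five feature stages,
# written as HDF5 for arrays plus TSV/JSON for scalars, one file per
# feature following the sub-<label>_<feature>[_<measure>_<band>] naming
# scheme. The resolved parameter set is always written alongside.

#' Assemble a feature bundle
#'
#' @param subject subject label
#' @param spectrum a `power_spectrum`
#' @param apf list with `peak_maximum_hz` (may be NA) and `cog_hz`
#' @param source_power named list band -> per-ROI power vector
#' @param connectivity named list "measure_band" -> `connectivity_matrix`
#' @param graphs named list "measure_band" -> `graph_metrics`
#' @param params the resolved `eeg_params`
#' @param runlog optional preprocessing run log
#' @return a `feature_bundle`
#' @export
feature_bundle <- function(subject, spectrum, apf, source_power,
                           connectivity, graphs, params, runlog = NULL) {
  structure(list(subject = subject, spectrum = spectrum, apf = apf,
                 source_power = source_power, connectivity = connectivity,
                 graphs = graphs, params = params, runlog = runlog,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("resteeg")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
            class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat(sprintf("<feature_bundle> sub-%s: %d connectivity matrices, %d graph sets\n",
              x$subject, length(x$connectivity), length(x$graphs)))
  invisible(x)
}

h5_write_flat <- function(path, objects) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (nm in names(objects)) rhdf5::h5write(objects[[nm]], path, nm)
  rhdf5::h5closeAll()
}

#' Write a feature bundle to disk
#'
#' Emits `sub-<label>_power.h5`, `sub-<label>_peakfrequency.tsv`, one
#' `sub-<label>_<measure>_<band>.h5` per connectivity matrix, one
#' `sub-<label>_graph_<measure>_<band>.h5` per graph-metric set, a
#' one-row `sub-<label>_features.tsv` with the scalar features, and
#' `sub-<label>_params.json` with the resolved parameters.
#'
#' @param bundle a `feature_bundle`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the vector of written paths
#' @export
write_feature_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  stem <- file.path(out_dir, paste0("sub-", bundle$subject))
  paths <- character()
  ps <- bundle$spectrum
  p <- paste0(stem, "_power.h5")
  h5_write_flat(p, list(frequencies = ps$freq, power = ps$power,
                        global_power = ps$global,
                        channel_names = ps$channel_names,
                        n_epochs = ps$n_epochs))
  paths <- c(paths, p)
  p <- paste0(stem, "_peakfrequency.tsv")
  write_tsv_plain(data.frame(peak_maximum_hz = bundle$apf$peak_maximum_hz,
                             cog_hz = bundle$apf$cog_hz), p)
  paths <- c(paths, p)
  for (nm in names(bundle$connectivity)) {
    cm <- bundle$connectivity[[nm]]
    p <- paste0(stem, "_", nm, ".h5")
    h5_write_flat(p, list(matrix = cm$matrix, roi_names = cm$roi_names,
                          band = cm$band, measure = cm$measure))
    paths <- c(paths, p)
  }
  for (nm in names(bundle$graphs)) {
    gm <- bundle$graphs[[nm]]
    p <- paste0(stem, "_graph_", nm, ".h5")
    h5_write_flat(p, list(degree = gm$local$degree,
                          clustering = gm$local$clustering,
                          node_names = gm$local$node,
                          global_clustering = gm$global$global_clustering,
                          global_efficiency = gm$global$global_efficiency,
                          smallworldness = gm$global$smallworldness,
                          density = gm$density,
                          n_null = gm$null_model$n_null,
                          null_seed = gm$null_model$seed))
    paths <- c(paths, p)
  }
  if (length(bundle$source_power)) {
    p <- paste0(stem, "_sourcepower.h5")
    h5_write_flat(p, bundle$source_power)
    paths <- c(paths, p)
  }
  # scalar summary row
  scal <- data.frame(subject = bundle$subject,
                     peak_maximum_hz = bundle$apf$peak_maximum_hz,
                     cog_hz = bundle$apf$cog_hz)
  for (nm in names(bundle$graphs)) {
    g <- bundle$graphs[[nm]]$global
    scal[[paste0(nm, "_clustering")]] <- g$global_clustering
    scal[[paste0(nm, "_efficiency")]] <- g$global_efficiency
    scal[[paste0(nm, "_smallworldness")]] <- g$smallworldness
  }
  p <- paste0(stem, "_features.tsv")
  write_tsv_plain(scal, p)
  paths <- c(paths, p)
  p <- paste0(stem, "_params.json")
  write_params(bundle$params, p)
  paths <- c(paths, p)
  if (!is.null(bundle$runlog)) {
    p <- paste0(stem, "_runlog.json")
    jsonlite::write_json(bundle$runlog, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back the array features of a written bundle
#'
#' @param out_dir directory written by [write_feature_bundle()]
#' @param subject subject label
#' @return list with `power` (frequencies, power, global), `connectivity`
#'   (named matrices), `graphs` (named lists), `apf`, `params`
#' @export
read_feature_bundle <- function(out_dir, subject) {
  stem <- file.path(out_dir, paste0("sub-", subject))
  pow <- rhdf5::h5dump(paste0(stem, "_power.h5"))
  files <- list.files(out_dir, pattern = paste0("^sub-", subject, "_.*\\.h5$"))
  conn <- list(); graphs <- list(); spow <- NULL
  for (f in files) {
    nm <- sub(paste0("^sub-", subject, "_"), "", sub("\\.h5$", "", f))
    if (nm %in% c("power")) next
    d <- rhdf5::h5dump(file.path(out_dir, f))
    if (nm == "sourcepower") spow <- d
    else if (grepl("^graph_", nm)) graphs[[sub("^graph_", "", nm)]] <- d
    else conn[[nm]] <- d$matrix
  }
  apf <- read_tsv_plain(paste0(stem, "_peakfrequency.tsv"))
  params <- jsonlite::read_json(paste0(stem, "_params.json"), simplifyVector = TRUE)
  rhdf5::h5closeAll()
  list(power = pow, connectivity = conn, graphs = graphs,
       source_power = spow, apf = apf, params = params)
}
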