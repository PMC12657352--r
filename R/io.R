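# File formats: network JSON, waveform/division/results CSV, run manifests.

#' Write / read an aortic network as JSON
#'
#' Schema: `{"segments": [{"id","from","to","length_cm","radius_cm",
#' "lumen_tag","stenosis":{"area_ratio","kt"},"branch","station",
#' "dilation"}], "inlet": "...", "outlets": {"BT": "n01", ...}}`. Optional
#' per-segment keys (`stenosis`, `branch`, `station`, `dilation`) are
#' omitted when at their defaults; reading validates the schema and names
#' the offending field in errors.
#'
#' @param net an `aortic_network`.
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a validated `aortic_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "aortic_network"))
  seg <- net$segments
  segs <- lapply(seq_len(nrow(seg)), function(i) {
    s <- list(id = seg$id[i], from = seg$from[i], to = seg$to[i],
              length_cm = seg$length_cm[i], radius_cm = seg$radius_cm[i],
              lumen_tag = seg$lumen_tag[i])
    if (!is.na(seg$sten_area_ratio[i]))
      s$stenosis <- list(area_ratio = seg$sten_area_ratio[i], kt = seg$sten_kt[i])
    if (!is.na(seg$branch[i])) s$branch <- seg$branch[i]
    if (!is.na(seg$station[i])) s$station <- seg$station[i]
    if (seg$dilation[i] != 1) s$dilation <- seg$dilation[i]
    s
  })
  jsonlite::write_json(list(segments = segs, inlet = net$inlet,
                            outlets = as.list(net$outlets)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) fd_io_error(sprintf("network file not found: %s", path))
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) fd_io_error(sprintf(
                  "cannot parse network JSON '%s': %s", path, conditionMessage(e))))
  for (f in c("segments", "inlet", "outlets"))
    if (is.null(j[[f]]))
      fd_validation_error(sprintf("network JSON missing field '%s'", f))
  need <- c("id", "from", "to", "length_cm", "radius_cm")
  seg <- do.call(rbind, lapply(j$segments, function(s) {
    miss <- setdiff(need, names(s))
    if (length(miss))
      fd_validation_error(sprintf("segment missing field(s): %s",
                                  paste(miss, collapse = ", ")))
    new_segment_table(
      id = s$id, from = s$from, to = s$to,
      length_cm = as.numeric(s$length_cm), radius_cm = as.numeric(s$radius_cm),
      lumen_tag = if (is.null(s$lumen_tag)) "NONE" else s$lumen_tag,
      branch = if (is.null(s$branch)) NA_character_ else s$branch,
      station = if (is.null(s$station)) NA_integer_ else as.integer(s$station),
      sten_area_ratio = if (is.null(s$stenosis)) NA_real_
                        else as.numeric(s$stenosis$area_ratio),
      sten_kt = if (is.null(s$stenosis)) NA_real_
                else as.numeric(s$stenosis$kt),
      dilation = if (is.null(s$dilation)) 1 else as.numeric(s$dilation))
  }))
  outlets <- unlist(j$outlets)
  aortic_network(seg, inlet = j$inlet, outlets = outlets)
}

#' Write a flow division as CSV
#'
#' Columns `branch, fraction`.
#'
#' @param division a [flow_division()] (or named fractions).
#' @param path file path.
#' @export
write_division <- function(division, path) {
  d <- unclass(division)
  utils::write.csv(data.frame(branch = names(d), fraction = unname(d)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_division
#' @export
read_division <- function(path) {
  if (!file.exists(path)) fd_io_error(sprintf("division file not found: %s", path))
  d <- utils::read.csv(path)
  if (!all(c("branch", "fraction") %in% names(d)))
    fd_validation_error("division CSV needs columns 'branch' and 'fraction'")
  flow_division(stats::setNames(d$fraction, d$branch))
}

#' Write / read an inlet waveform as CSV
#'
#' Columns `time_s, flow_mL_s`.
#'
#' @param waveform an [inlet_waveform()].
#' @param path file path.
#' @export
write_waveform <- function(waveform, path) {
  wf <- as_inlet_waveform(waveform)
  utils::write.csv(data.frame(time_s = wf$time, flow_mL_s = wf$flow),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) fd_io_error(sprintf("waveform file not found: %s", path))
  as_inlet_waveform(utils::read.csv(path))
}

#' Write a steady result as CSV + JSON summary
#'
#' CSV columns `branch, Q_mL_s, P_out_mmHg, dP_mmHg`; the JSON summary
#' carries `P_in` and the inlet flow.
#'
#' @param result a `steady_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_steady_result <- function(result, csv_path, json_path = NULL) {
  stopifnot(inherits(result, "steady_result"))
  if (!is.null(csv_path))
    utils::write.csv(data.frame(branch = names(result$Q),
                                Q_mL_s = unname(result$Q),
                                P_out_mmHg = unname(result$P_out),
                                dP_mmHg = unname(result$dP)),
                     csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(P_in_mmHg = result$P_in,
                              inlet_flow_mL_s = result$inlet_flow,
                              n_iter = result$n_iter),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' Write an iteration trace as JSON
#'
#' @param trace an `iteration_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "iteration_trace"))
  jsonlite::write_json(list(converged = trace$converged, n_iter = trace$n_iter,
                            threshold = trace$threshold,
                            records = trace$records),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write Windkessel parameters as JSON
#'
#' @param wk3_map named list of [windkessel3()] objects.
#' @param path file path.
#' @export
write_wk3 <- function(wk3_map, path) {
  jsonlite::write_json(lapply(wk3_map, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the run: config digest (md5 of its serialized JSON),
#' package version, R version, seed, and timestamp-free reproducibility
#' fields.
#'
#' @param config an `fd_config`.
#' @param path file path.
#' @param extra named list of extra fields to record.
#' @export
write_manifest <- function(config, path, extra = list()) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  cfg_json <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  digest <- unname(tools::md5sum(tf)); unlink(tf)
  jsonlite::write_json(c(list(config_md5 = digest, seed = config$seed,
                              package = "flowdiv",
                              version = as.character(utils::packageVersion("flowdiv")),
                              r_version = paste(R.version$major, R.version$minor,
                                                sep = ".")),
                         extra),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
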