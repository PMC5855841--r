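# On-disk interchange for synthetic recordings: one CSV per sweep with
# comment-prefixed metadata header lines, plus a JSON group manifest.

sweep_filename <- function(cell_id, sweep) {
  sprintf("%s_%s_%+04dmV.csv", cell_id, sweep$protocol_name,
          as.integer(round(sweep$test_voltage)))
}

#' Write one sweep to CSV
#'
#' Metadata travels in `# key: value` comment lines (cell_id, condition,
#' capacitance_pF, protocol, seed), followed by columns `time_ms`,
#' `voltage_mV`, `current_pA`.
#'
#' @param sweep A `sweep`.
#' @param recording The owning `cell_recording` (metadata source).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cell_id: %s", recording$cell_id),
    sprintf("# condition: %s", recording$condition),
    sprintf("# capacitance_pF: %s", fmt_num(recording$capacitance_pF)),
    sprintf("# protocol: %s", sweep$protocol_name),
    sprintf("# seed: %d", recording$seed),
    "time_ms,voltage_mV,current_pA"), con)
  writeLines(sprintf("%s,%s,%s", fmt_num(sweep$time_ms),
                     fmt_num(rep(sweep$test_voltage,
                                 length(sweep$time_ms))),
                     fmt_num(sweep$current_pA)), con)
  invisible(path)
}

#' Read one sweep CSV back
#'
#' @param path CSV written by [write_sweep_csv()].
#' @return List with `sweep` (a `sweep` object) and `meta` (named list of
#'   the header metadata).
#' @export
read_sweep_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    meta[[trimws(m[2])]] <- trimws(m[3])
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  sweep <- structure(list(test_voltage = as.numeric(tab$voltage_mV[1]),
                          time_ms = as.numeric(tab$time_ms),
                          current_pA = as.numeric(tab$current_pA),
                          protocol_name = meta$protocol),
                     class = "sweep")
  list(sweep = sweep, meta = meta)
}

#' Write a condition group (sweep CSVs + JSON manifest)
#'
#' @param group Output of [generate_condition_group()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_group <- function(group, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (rec in group$recordings) {
    fl <- vapply(rec$sweeps, function(s) {
      f <- sweep_filename(rec$cell_id, s)
      write_sweep_csv(s, rec, file.path(dir, f))
      f
    }, "")
    files[[rec$cell_id]] <- list(capacitance_pF = rec$capacitance_pF,
                                 seed = rec$seed, sweeps = fl)
  }
  manifest <- c(group$manifest, list(files = files))
  mpath <- file.path(dir, "manifest.json")
  # digits = I(17): 17 significant digits, enough for exact double
  # round-tripping (digits = NA truncates to 15 in this jsonlite)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a condition group back from disk
#'
#' @param dir Directory written by [write_group()].
#' @return List with `recordings` (list of `cell_recording`, without model
#'   parameters) and `manifest`.
#' @export
read_group <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  recordings <- lapply(names(manifest$files), function(cid) {
    entry <- manifest$files[[cid]]
    sweeps <- lapply(unlist(entry$sweeps), function(f)
      read_sweep_csv(file.path(dir, f))$sweep)
    structure(list(cell_id = cid, condition = manifest$preset,
                   capacitance_pF = entry$capacitance_pF,
                   seed = entry$seed, params = NULL,
                   sweeps = unname(sweeps)),
              class = "cell_recording")
  })
  list(recordings = recordings, manifest = manifest)
}
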