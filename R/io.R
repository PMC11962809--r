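# Minimal WFDB (PhysioNet) format-16 interoperability: one .hea header and
# one interleaved little-endian int16 .dat per record. Only the subset of
# the header grammar needed for 500 Hz multi-lead rhythm records is
# implemented; age, sex, label and source travel as '# key: value' comment
# lines, and diagnostic codes as '# Dx: code1,code2'.

#' Write one record as a WFDB format-16 pair
#'
#' @param record an [ecg_record()].
#' @param dir output directory.
#' @param gain analog-to-digital gain in units per mV (default 1000, i.e.
#'   1 uV resolution).
#' @return the header path, invisibly.
#' @export
write_wfdb_record <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- record$id
  n_sig <- nrow(record$signal)
  n_samp <- ncol(record$signal)
  dig <- round(record$signal * gain)
  dig <- pmin(pmax(dig, -32768), 32767)
  hea <- c(sprintf("%s %d %g %d", id, n_sig, record$fs, n_samp),
           sprintf("%s.dat 16 %g/mV 16 0 %d 0 0 %s",
                   id, gain, as.integer(dig[, 1]), record$lead_names),
           sprintf("# age: %s", format(record$age)),
           sprintf("# sex: %s", record$sex),
           sprintf("# label: %s", record$label),
           sprintf("# source: %s", record$source))
  writeLines(hea, file.path(dir, paste0(id, ".hea")))
  con <- file(file.path(dir, paste0(id, ".dat")), "wb")
  on.exit(close(con))
  # frame-interleaved: all leads of sample 1, then sample 2, ...
  writeBin(as.integer(dig), con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(id, ".hea")))
}

#' Read one WFDB format-16 record
#'
#' Signals are converted to mV with the stored gain and baseline; lead
#' names are mapped to canonical labels; age/sex are parsed from header
#' comments when present. The label comes from a `# label:` comment when
#' present, otherwise from `label_table` applied to the record's `# Dx:`
#' codes (any positive code makes the record positive); with neither, the
#' label is `NA` and cohort readers skip the record.
#'
#' @param hea_path path to the `.hea` file.
#' @param label_table optional data.frame with columns `code` and `label`
#'   (`"AF_positive"` / `"negative"`).
#' @return an [ecg_record()] (label possibly `NA`).
#' @export
read_wfdb_record <- function(hea_path, label_table = NULL) {
  lines <- readLines(hea_path, warn = FALSE)
  if (!length(lines)) stop("empty WFDB header: ", hea_path, call. = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("corrupt WFDB header: ", hea_path, call. = FALSE)
  id <- top[1]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  if (is.na(n_sig) || is.na(fs) || is.na(n_samp))
    stop("corrupt WFDB header: ", hea_path, call. = FALSE)
  sig_lines <- lines[2:(1 + n_sig)]
  comments <- grep("^#", lines, value = TRUE)

  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 3 || tok[2] != "16")
      stop("only WFDB format 16 is supported (", hea_path, ")", call. = FALSE)
    gm <- regmatches(tok[3], regexec("^([-0-9.eE+]+)(\\(([-0-9.]+)\\))?(/mV)?$",
                                     tok[3]))[[1]]
    gain <- as.numeric(gm[2])
    baseline <- if (nzchar(gm[4])) as.numeric(gm[4]) else 0
    if (is.na(gain) || gain == 0) gain <- 200 # WFDB default gain
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else NA_character_
    list(file = tok[1], gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat_file <- sigs[[1]]$file
  dat_path <- file.path(dirname(hea_path), dat_file)
  raw <- readBin(dat_path, integer(), n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  dig <- matrix(raw, nrow = n_sig) # frame-interleaved
  analog <- (dig - vapply(sigs, `[[`, 0, "baseline")) /
    vapply(sigs, `[[`, 0, "gain")
  lead_names <- toupper(vapply(sigs, `[[`, "", "desc"))
  lead_names[is.na(lead_names)] <- paste0("SIG", which(is.na(lead_names)))

  get_comment <- function(key) {
    ln <- grep(sprintf("^#\\s*%s\\s*:", key), comments, value = TRUE,
               ignore.case = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", ln[1], ignore.case = TRUE))
  }
  age <- suppressWarnings(as.numeric(get_comment("age")))
  sex <- tolower(get_comment("sex"))
  if (!sex %in% c("male", "female")) sex <- NA_character_
  label <- get_comment("label")
  if (is.na(label) && !is.null(label_table)) {
    dx <- get_comment("Dx")
    if (!is.na(dx)) {
      codes <- trimws(strsplit(dx, ",")[[1]])
      hit <- label_table$label[match(codes, as.character(label_table$code))]
      if (all(is.na(hit))) label <- NA_character_
      else label <- if (any(hit == "AF_positive", na.rm = TRUE)) "AF_positive"
                    else "negative"
    }
  }
  src <- get_comment("source")
  ecg_record(analog, lead_names, fs, age = age, sex = sex,
             label = label, source = if (is.na(src)) "wfdb" else src,
             id = id)
}

#' Write a cohort as WFDB records plus a CSV manifest
#'
#' @param cohort list with `records` and `manifest`, as from
#'   [generate_cohort()].
#' @param dir output directory.
#' @param gain units per mV.
#' @return the directory, invisibly.
#' @export
write_wfdb_cohort <- function(cohort, dir, gain = 1000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records) write_wfdb_record(rec, dir, gain = gain)
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a directory of WFDB records
#'
#' Records whose label cannot be resolved are skipped with a message.
#'
#' @param dir directory of `.hea`/`.dat` pairs.
#' @param label_table optional diagnostic-code mapping (see
#'   [read_wfdb_record()]).
#' @return list of [ecg_record()].
#' @export
read_wfdb_cohort <- function(dir, label_table = NULL) {
  heas <- sort(list.files(dir, pattern = "\\.hea$", full.names = TRUE))
  out <- list()
  for (h in heas) {
    rec <- read_wfdb_record(h, label_table)
    if (is.na(rec$label)) {
      message("skipping ", rec$id, ": no label entry")
      next
    }
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Template label table for PhysioNet-style diagnostic codes
#'
#' Returns a skeleton mapping with the SNOMED-style slots for AF and AFL
#' codes filled as positive; extend or replace the codes to match the
#' archive being read.
#'
#' @return data.frame with columns `code` and `label`.
#' @export
label_table_template <- function() {
  data.frame(code = c("164889003", "164890007", "426783006"),
             label = c("AF_positive", "AF_positive", "negative"),
             stringsAsFactors = FALSE)
}
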