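# WFDB-convention record IO: .hea header, format-16 .dat signal, MIT-format
# .atr annotations. Scope: single- and multi-lead format-16 records with a
# scalar gain/baseline per signal, which covers the package's own
# serialization and the common arrhythmia-archive layout. Sample indices
# are 0-based throughout.

# MIT annotation code <-> symbol table (the commonly used subset).
.ann_codes <- c("N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L,
                "F" = 6L, "J" = 7L, "A" = 8L, "S" = 9L, "E" = 10L,
                "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L, "|" = 16L,
                "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L, "\"" = 22L,
                "=" = 23L, "p" = 24L, "B" = 25L, "^" = 26L, "t" = 27L,
                "+" = 28L, "u" = 29L, "?" = 30L, "!" = 31L, "[" = 32L,
                "]" = 33L, "e" = 34L, "n" = 35L, "@" = 36L, "x" = 37L,
                "f" = 38L, "(" = 39L, ")" = 40L, "r" = 41L)
.ann_skip <- 59L

symbol_to_code <- function(symbol) {
  code <- unname(.ann_codes[symbol])
  code[is.na(code)] <- .ann_codes[["Q"]]  # unknown beat symbol
  code
}

code_to_symbol <- function(code) {
  sym <- names(.ann_codes)[match(code, .ann_codes)]
  sym[is.na(sym)] <- "Q"
  sym
}

#' Write a record as WFDB-convention files
#'
#' Serializes a record as a `.hea` header, a format-16 (16-bit little-endian
#' two's-complement) `.dat` signal file, and a MIT-format `.atr` annotation
#' file, under the record id as base name. Amplitudes are quantized with
#' the written ADC gain (`adc_gain` units per mV, baseline 0); reading the
#' files back reproduces the quantized samples bit-exactly.
#'
#' @param rec an [ecg_record()].
#' @param dir directory to write into (created if needed).
#' @param adc_gain ADC units per mV used for quantization.
#' @param aux_leads optional named list of additional numeric signals (same
#'   length as `rec$samples`) stored as further leads of the same record.
#' @return invisibly, the path prefix (without extension) of the record.
#' @export
write_record <- function(rec, dir, adc_gain = 200, aux_leads = NULL) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, rec$record_id)
  sigs <- c(stats::setNames(list(rec$samples), rec$lead_name), aux_leads)
  nsig <- length(sigs)
  n <- length(rec$samples)
  if (!all(vapply(sigs, length, integer(1)) == n)) {
    stop("all leads must have the same length")
  }
  adc <- lapply(sigs, function(x) {
    v <- as.integer(round(x * adc_gain))
    clamp(v, -32768L, 32767L)
  })
  # header
  fs_txt <- format(rec$fs, digits = 12)
  hea <- c(sprintf("%s %d %s %d", rec$record_id, nsig, fs_txt, n),
           vapply(seq_len(nsig), function(i) {
             sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                     rec$record_id, adc_gain, adc[[i]][1], names(sigs)[i])
           }, character(1)),
           sprintf("# subject: %s", rec$subject_id))
  writeLines(hea, paste0(base, ".hea"))
  # signal: interleaved int16 little-endian
  inter <- integer(n * nsig)
  for (i in seq_len(nsig)) inter[seq(i, by = nsig, length.out = n)] <- adc[[i]]
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(inter, con, size = 2L, endian = "little")
  close(con)
  write_annotations(rec$annotations$sample, rec$annotations$symbol,
                    paste0(base, ".atr"))
  invisible(base)
}

#' Read a WFDB-convention record
#'
#' Reads the `.hea`/`.dat`/`.atr` triplet at `path` (the record path
#' without extension), returning the requested lead in mV with all beat
#' annotations attached at the native sampling rate.
#'
#' @param path record path prefix (no extension).
#' @param lead lead name to extract, as written in the header signal
#'   description; defaults to the first lead.
#' @param ... passed to [map_annotation_symbol()] for labelling.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, lead = NULL, ...) {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("header file not found: ", hea_path)
  hea <- readLines(hea_path)
  hea_body <- hea[!grepl("^\\s*#", hea) & nzchar(trimws(hea))]
  top <- strsplit(trimws(hea_body[1]), "\\s+")[[1]]
  record_id <- top[1]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- hea_body[seq(2, length.out = nsig)]
  sig <- lapply(sig_lines, parse_signal_line)
  leads <- vapply(sig, `[[`, character(1), "description")
  li <- if (is.null(lead)) 1L else match(lead, leads)
  if (is.na(li)) {
    stop(sprintf("lead '%s' not present; available leads: %s",
                 lead, paste(leads, collapse = ", ")))
  }
  fmts <- vapply(sig, `[[`, character(1), "format")
  if (!all(fmts == "16")) {
    stop("only format 16 signal files are supported (got format ",
         paste(unique(fmts), collapse = ","), ")")
  }
  dat_path <- paste0(dirname(path), "/", sig[[li]]$file)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  con <- file(dat_path, "rb")
  raw_n <- file.info(dat_path)$size / 2
  inter <- readBin(con, "integer", n = raw_n, size = 2L, signed = TRUE,
                   endian = "little")
  close(con)
  n <- length(inter) %/% nsig
  if (!is.na(nsamp)) n <- min(n, nsamp)
  adc <- inter[seq(li, by = nsig, length.out = n)]
  mv <- (adc - sig[[li]]$baseline) / sig[[li]]$gain
  atr_path <- paste0(path, ".atr")
  ann <- if (file.exists(atr_path)) read_annotations(atr_path) else
    data.frame(sample = integer(0), symbol = character(0))
  subject_id <- record_id
  subj_line <- grep("^# subject:", hea, value = TRUE)
  if (length(subj_line) > 0) subject_id <- trimws(sub("^# subject:", "", subj_line[1]))
  ecg_record(record_id = record_id, subject_id = subject_id,
             lead_name = leads[li], fs = fs, samples = mv,
             annotations = ann, ...)
}

parse_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  gain_spec <- if (length(tok) >= 3) tok[3] else "200"
  gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_spec)))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- 0
  m <- regmatches(gain_spec, regexec("\\(([-0-9]+)\\)", gain_spec))[[1]]
  if (length(m) == 2) baseline <- as.numeric(m[2])
  desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else tok[1]
  list(file = tok[1], format = tok[2], gain = gain, baseline = baseline,
       description = desc)
}

# MIT-format annotation writer: 2-byte words, type in the high 6 bits,
# time increment from the previous annotation in the low 10 bits; long
# intervals use a SKIP word followed by the 4-byte interval (high word
# first, each word little-endian); a zero word terminates the file.
write_annotations <- function(samples, symbols, path) {
  stopifnot(length(samples) == length(symbols))
  codes <- symbol_to_code(symbols)
  words <- integer(0)
  prev <- 0L
  for (i in seq_along(samples)) {
    delta <- as.integer(samples[i]) - prev
    if (delta < 0) stop("annotation samples must be non-decreasing")
    if (delta > 1023L) {
      words <- c(words, bitwShiftL(.ann_skip, 10),
                 delta %/% 65536L, delta %% 65536L)
      delta <- 0L
    }
    words <- c(words, bitwShiftL(codes[i], 10) + delta)
    prev <- as.integer(samples[i])
  }
  words <- c(words, 0L)
  con <- file(path, "wb")
  # write as unsigned 16-bit: map >32767 into the signed range
  w <- ifelse(words > 32767L, words - 65536L, words)
  writeBin(as.integer(w), con, size = 2L, endian = "little")
  close(con)
  invisible(path)
}

read_annotations <- function(path) {
  con <- file(path, "rb")
  raw_n <- file.info(path)$size / 2
  w <- readBin(con, "integer", n = raw_n, size = 2L, signed = FALSE,
               endian = "little")
  close(con)
  samples <- integer(0); codes <- integer(0)
  t <- 0L; i <- 1L
  while (i <= length(w)) {
    word <- w[i]
    code <- word %/% 1024L
    tim <- word %% 1024L
    if (word == 0L) break
    if (code == .ann_skip) {
      delta <- w[i + 1L] * 65536L + w[i + 2L]
      t <- t + delta
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { i <- i + 1L; next }       # NUM/SUB/CHN
    if (code == 63L) { i <- i + 1L + (tim + tim %% 2L) %/% 2L; next }  # AUX
    t <- t + tim
    samples <- c(samples, t)
    codes <- c(codes, code)
    i <- i + 1L
  }
  data.frame(sample = samples, symbol = code_to_symbol(codes),
             stringsAsFactors = FALSE)
}
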