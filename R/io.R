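## Delimited-text layouts for every table the pipeline exchanges, each with
## a commented header recording the settings that produced it, plus a
## minimal NMR-STAR chemical-shift-loop reader for BMRB deposits.

.write_table_with_header <- function(df, path, settings = list()) {
  hdr <- c(sprintf("# relaxfit %s", as.character(utils::packageVersion("relaxfit"))),
           vapply(names(settings), function(k)
             sprintf("# %s: %s", k, paste(format(settings[[k]]), collapse = " ")),
             character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  settings <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1]]
    if (length(m) == 3) settings[[m[2]]] <- m[3]
  }
  attr(df, "settings") <- settings
  df
}

#' Write / read a relaxation-rate table
#'
#' Tab-delimited layout (residue_id, R1, R1_err, R2, R2_err, NOE, NOE_err)
#' with a commented header recording the field strength and any fit
#' settings.
#'
#' @param records A [relax_table()].
#' @param path Output path.
#' @param settings Named list written into the header.
#' @return `path` (write) or a [relax_table()] (read).
#' @export
write_relax_table <- function(records, path, settings = list()) {
  stopifnot(inherits(records, "relax_table"))
  field <- attr(records, "field")
  settings$proton_frequency_MHz <- field$proton_frequency_MHz
  .write_table_with_header(as.data.frame(records), path, settings)
}

#' @rdname write_relax_table
#' @export
read_relax_table <- function(path) {
  df <- .read_table_with_header(path)
  mhz <- as.numeric(attr(df, "settings")$proton_frequency_MHz)
  if (!is.finite(mhz)) stop("header lacks proton_frequency_MHz")
  relax_table(df$residue_id, df$R1, df$R1_err, df$R2, df$R2_err,
              df$NOE, df$NOE_err, field_spec(mhz))
}

#' Write / read a decay-series table
#'
#' Long layout: residue_id, delay_ms, intensity, noise_sigma.
#'
#' @param decays data.frame in the long layout.
#' @param path File path.
#' @param settings Header entries.
#' @return `path` (write) or the data.frame (read).
#' @export
write_decays <- function(decays, path, settings = list()) {
  .write_table_with_header(decays, path, settings)
}

#' @rdname write_decays
#' @export
read_decays <- function(path) .read_table_with_header(path)

#' Read an amide peak list from delimited text
#'
#' Layout: residue_id, delta_H, delta_N; `NA` shifts mark missing residues.
#'
#' @param path File path.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path) {
  df <- .read_table_with_header(path)
  peak_list(df$residue_id, df$delta_H, df$delta_N)
}

#' Write an amide peak list
#'
#' @param peaks A [peak_list()].
#' @param path File path.
#' @param settings Header entries.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path, settings = list()) {
  .write_table_with_header(as.data.frame(peaks), path, settings)
}

#' Read one loop from an NMR-STAR file
#'
#' Minimal NMR-STAR `loop_` parser: locates the first loop whose tags start
#' with `prefix` and returns its rows as a data.frame of character columns
#' named by the part after the dot. Sufficient for BMRB chemical-shift and
#' relaxation loops; not a general STAR parser (no multi-line values).
#'
#' @param path NMR-STAR file.
#' @param prefix Tag prefix, e.g. `"_Atom_chem_shift"`.
#' @return data.frame (character columns).
#' @export
read_star_loop <- function(path, prefix) {
  lines <- trimws(readLines(path))
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "loop_") {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        tags <- c(tags, lines[j])
        j <- j + 1L
      }
      if (length(tags) > 0 && all(startsWith(tags, prefix))) {
        rows <- list()
        while (j <= n && lines[j] != "stop_") {
          if (nzchar(lines[j]) && !startsWith(lines[j], "#")) {
            v <- scan(text = lines[j], what = character(), quiet = TRUE)
            rows[[length(rows) + 1L]] <- v
          }
          j <- j + 1L
        }
        if (length(rows) == 0) stop("empty loop for prefix ", prefix)
        mat <- do.call(rbind, rows)
        if (ncol(mat) != length(tags))
          stop("loop row width does not match tag count")
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- sub(paste0("^", prefix, "\\."), "", tags)
        return(df)
      }
      i <- j
    }
    i <- i + 1L
  }
  stop("no loop with prefix ", prefix, " in ", path)
}

#' Read amide shifts from an NMR-STAR chemical-shift loop
#'
#' Extracts backbone H and N shifts from an `_Atom_chem_shift` loop and
#' pairs them per residue into a [peak_list()]. Residues with only one of
#' the two shifts are treated as missing.
#'
#' @param path NMR-STAR file.
#' @return A [peak_list()].
#' @export
read_nmrstar_shifts <- function(path) {
  df <- read_star_loop(path, "_Atom_chem_shift")
  seq_col <- intersect(c("Seq_ID", "Comp_index_ID"), names(df))[1]
  if (is.na(seq_col)) stop("chemical-shift loop lacks a sequence-id tag")
  atom <- df$Atom_ID
  val <- as.numeric(df$Val)
  resno <- as.integer(df[[seq_col]])
  keep <- atom %in% c("H", "HN", "N")
  resno <- resno[keep]; atom <- atom[keep]; val <- val[keep]
  ids <- sort(unique(resno))
  dH <- dN <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    sel <- resno == ids[k]
    h <- val[sel & atom %in% c("H", "HN")]
    nn <- val[sel & atom == "N"]
    if (length(h) > 0) dH[k] <- h[1]
    if (length(nn) > 0) dN[k] <- nn[1]
  }
  peak_list(ids, dH, dN)
}
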