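#' Read a TCK streamline file
#'
#' Reads the MRtrix track format: an ASCII header (`mrtrix tracks`,
#' `key: value` lines, terminated by `END`) followed by little-endian
#' float32 triplets in world-space mm; `NaN` triplets separate streamlines
#' and an `Inf` triplet ends the stream.
#'
#' @param path File path.
#' @param name Bundle label (default: file name without extension).
#' @return A [streamline_bundle()] (possibly with zero streamlines); the
#'   parsed header is attached as attribute `header`.
#' @export
read_tck <- function(path, name = sub("\\.tck$", "", basename(path))) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 14 ||
      rawToChar(raw[1:14]) != "mrtrix tracks\n")
    stop("not a TCK file (missing 'mrtrix tracks' magic): ", path)
  # locate END of header
  txt_end <- NA_integer_
  for (i in seq_len(min(length(raw), 65536L) - 3L)) {
    if (raw[i] == as.raw(0x45) && raw[i + 1] == as.raw(0x4e) &&
        raw[i + 2] == as.raw(0x44) && raw[i + 3] == as.raw(0x0a)) {
      txt_end <- i + 3L; break
    }
  }
  if (is.na(txt_end)) stop("TCK header not terminated by END: ", path)
  header_lines <- strsplit(rawToChar(raw[1:txt_end]), "\n")[[1]]
  kv <- grep(":", header_lines, value = TRUE)
  keys <- sub(":.*", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  header <- stats::setNames(as.list(vals), keys)
  dt <- header[["datatype"]]
  if (!is.null(dt) && !(dt %in% c("Float32LE")))
    stop("unsupported TCK datatype '", dt, "' (only Float32LE)")
  off_field <- header[["file"]]
  if (is.null(off_field)) stop("TCK header has no 'file' field: ", path)
  offset <- as.integer(sub("^\\.\\s*", "", off_field))
  if (is.na(offset) || offset > length(raw))
    stop("invalid TCK data offset at byte ", txt_end, ": ", path)
  nfl <- (length(raw) - offset) %/% 4L
  if (nfl %% 3L != 0L)
    stop("truncated TCK float stream at byte ", offset, ": ", path)
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric", n = nfl,
                  size = 4L, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(m)) > 0
  is_inf <- rowSums(is.infinite(m)) > 0
  breaks <- which(is_nan | is_inf)
  streamlines <- list()
  start <- 1L
  for (b in c(breaks, nrow(m) + 1L)) {
    if (b > start) {
      streamlines[[length(streamlines) + 1L]] <-
        m[start:(b - 1L), , drop = FALSE]
    }
    start <- b + 1L
    if (b <= nrow(m) && is_inf[b]) break
  }
  out <- if (length(streamlines) == 0)
    structure(list(name = name, streamlines = list()),
              class = "streamline_bundle")
  else streamline_bundle(streamlines, name)
  attr(out, "header") <- header
  out
}

#' Write a TCK streamline file
#'
#' @param bundle A [streamline_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(bundle, path) {
  count <- length(bundle$streamlines)
  base <- paste0("mrtrix tracks\n",
                 "datatype: Float32LE\n",
                 "count: ", count, "\n")
  # the 'file: . <offset>' line includes the offset of the binary section,
  # which depends on its own length; iterate to a fixed point
  offset <- nchar(base) + nchar("file: . \nEND\n") + 1L
  repeat {
    header <- paste0(base, "file: . ", offset, "\nEND\n")
    if (nchar(header) == offset) break
    offset <- nchar(header)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in bundle$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a 4D NIfTI volume as an FOD or tensor field
#'
#' The affine is taken from the file's preferred transform (sform over
#' qform, RNifti's default); the 4th dimension must hold a valid even-order
#' spherical-harmonic coefficient count (`kind = "sh"`) or 6 tensor
#' components in (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz) order (`kind = "tensor"`).
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param kind `"sh"` or `"tensor"`.
#' @return A [fod_field()] or [tensor_field()].
#' @export
read_nifti_field <- function(path, kind = c("sh", "tensor")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4)
    stop("expected a 4D volume, found ", length(dim(arr)), "D: ", path)
  affine <- unclass(RNifti::xform(img))
  if (kind == "sh") {
    fod_field(arr, affine)  # validates the coefficient count
  } else {
    if (dim(arr)[4] != 6)
      stop("tensor volume must have 6 components in the 4th dimension, found ",
           dim(arr)[4], ": ", path)
    tensor_field(arr, affine)
  }
}

#' Write an FOD or tensor field as 4D NIfTI
#'
#' @param field A [fod_field()] or [tensor_field()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_nifti_field <- function(field, path) {
  arr <- if (inherits(field, "fod_field")) field$coefficients
         else field$tensors
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read the cohort table (TSV)
#'
#' Tab-separated, '.' decimal separator, explicit header with columns
#' `subject`, `group`, `hl_db`, `thi`, `duration_y`, `age_y`.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "hl_db", "thi", "duration_y", "age_y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Write / read a profile matrix (TSV)
#'
#' Rows are subjects, columns `seg000 .. segNNN`; the bundle and metric are
#' recorded in comment lines at the top of the file.
#'
#' @param m A [profile_matrix()].
#' @param path File path.
#' @return `path` (write) or the matrix with attributes restored (read).
#' @export
write_profile_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# bundle: ", attr(m, "bundle_name")),
               paste0("# metric: ", attr(m, "metric"))), con)
  df <- data.frame(subject = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 10)
  bn <- sub("^# bundle: ", "", grep("^# bundle: ", hdr, value = TRUE)[1])
  mt <- sub("^# metric: ", "", grep("^# metric: ", hdr, value = TRUE)[1])
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  profile_matrix(asplit(m, 1), df$subject, bn, mt)
}

#' Bundled reference tables
#'
#' `reference_group_differences()` returns the published per-bundle group
#' difference statistics of a chronic-tinnitus tractometry cohort (19
#' tinnitus vs 19 control subjects): minimum uncorrected p, its along-tract
#' segment, the t statistic, Cohen's d and post-hoc power, for the AFD,
#' FOD-peak-amplitude and FA analyses. `reference_cohort_demographics()`
#' returns the corresponding per-subject tinnitus-group demographics (age,
#' tinnitus laterality, duration, THI, origin, hearing loss). Both are
#' used to validate the package's effect-size conversions and synthetic
#' cohort distributions against published values.
#'
#' @return A data frame.
#' @export
reference_group_differences <- function() {
  utils::read.delim(system.file("extdata", "reference_group_differences.tsv",
                                package = "tractoprofile"),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_group_differences
#' @export
reference_cohort_demographics <- function() {
  utils::read.delim(system.file("extdata", "reference_cohort_demographics.tsv",
                                package = "tractoprofile"),
                    stringsAsFactors = FALSE)
}
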