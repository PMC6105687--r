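#' Read somatic substitutions from a VCF
#'
#' Retains biallelic SNVs only; indels and multi-allelic records are skipped
#' and their count logged (and attached as attribute `n_skipped`). Positions
#' are 1-based as in the file; chromosome names are normalized by stripping a
#' "chr" prefix. Per-sample ref/alt read depths are taken from the `AD`
#' FORMAT field.
#'
#' @param path VCF file (4.2; plain text or gzipped).
#' @param sample_id,timepoint labels attached to every record; `timepoint`
#'   must be `"SMM"` or `"MM"`.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `sample_id`, `timepoint`; attribute `n_skipped`.
#' @export
read_mutations <- function(path, sample_id, timepoint) {
  timepoint <- match.arg(timepoint, .tp_levels)
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ref_count = integer(0), alt_count = integer(0),
                      sample_id = character(0), timepoint = character(0))
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped > 0) {
    message(n_skipped, " non-SNV/multi-allelic record(s) skipped in ", path)
  }
  if (!any(snv)) {
    attr(empty, "n_skipped") <- as.integer(n_skipped)
    return(empty)
  }
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad) || all(is.na(ad))) {
    stop("missing AD depth field for sample ", sample_id, " in ", path)
  }
  ad <- ad[snv, 1]
  parts <- strsplit(ad, ",", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed AD field for sample ", sample_id)
  ref_count <- as.integer(vapply(parts, `[`, character(1), 1))
  alt_count <- as.integer(vapply(parts, `[`, character(1), 2))
  out <- data.frame(chrom = normalize_chrom(fix[snv, "CHROM"]),
                    pos = as.integer(fix[snv, "POS"]),
                    ref = ref[snv], alt = alt[snv],
                    ref_count = ref_count, alt_count = alt_count,
                    sample_id = sample_id, timepoint = timepoint)
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

# cheap structural validation so malformed lines are reported with a line
# number before vcfR's own (less specific) parser runs
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0) return(invisible(TRUE))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- nfield < 8
  if (any(bad)) {
    stop(sprintf("malformed VCF line %d in %s (%d field(s))",
                 body[which(bad)[1]], path, nfield[which(bad)[1]]))
  }
  invisible(TRUE)
}

#' Write substitutions as a minimal VCF 4.2
#'
#' Fixed 10-column layout with ref/alt read depths in the `AD` FORMAT field
#' (plus `DP`); INFO is left empty. Coordinates are written 1-based as
#' stored.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`.
#' @param path output file.
#' @param sample_id column header for the single sample.
#' @param contigs optional named vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(mutations, path, sample_id, contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=smmevo",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t"))
  if (nrow(mutations) > 0) {
    o <- order(mutations$chrom, mutations$pos)
    m <- mutations[o, , drop = FALSE]
    body <- paste(m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS", ".",
                  "AD:DP",
                  paste0(m$ref_count, ",", m$alt_count, ":",
                         m$ref_count + m$alt_count),
                  sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read structural rearrangements from BEDPE
#'
#' Dialect: the 10 standard BEDPE columns (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2) followed by `support_reads`
#' and `total_reads`. The `name` column holds the rearrangement type; when it
#' does not, the type is inferred from the strand pair (+/- deletion, -/+
#' tandem duplication, +/+ or -/- inversion; interchromosomal records are
#' translocations). BEDPE coordinates are 0-based half-open; internally each
#' breakpoint is the 1-based position `end`.
#'
#' @param path BEDPE file.
#' @param sample_id,timepoint labels attached to every record.
#' @return data.frame with `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2`, `sv_type`, `support_reads`, `total_reads`, `sample_id`,
#'   `timepoint`.
#' @export
read_rearrangements <- function(path, sample_id, timepoint) {
  timepoint <- match.arg(timepoint, .tp_levels)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name",
            "score", "strand1", "strand2", "support_reads", "total_reads")
  empty <- data.frame(chrom1 = character(0), pos1 = integer(0),
                      strand1 = character(0), chrom2 = character(0),
                      pos2 = integer(0), strand2 = character(0),
                      sv_type = character(0), support_reads = integer(0),
                      total_reads = integer(0), sample_id = character(0),
                      timepoint = character(0))
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) < length(cols)) {
    stop("BEDPE file ", path, " has ", ncol(dt), " columns; expected ",
         length(cols))
  }
  names(dt)[seq_along(cols)] <- cols
  chrom1 <- normalize_chrom(dt$chrom1)
  chrom2 <- normalize_chrom(dt$chrom2)
  known <- c("deletion", "inversion", "tandem_duplication", "translocation")
  sv_type <- ifelse(dt$name %in% known, dt$name, NA_character_)
  inter <- chrom1 != chrom2
  strand_key <- paste0(dt$strand1, dt$strand2)
  inferred <- ifelse(inter, "translocation",
                     c("+-" = "deletion", "-+" = "tandem_duplication",
                       "++" = "inversion", "--" = "inversion")[strand_key])
  sv_type <- ifelse(is.na(sv_type), inferred, sv_type)
  bad_type <- inter != (sv_type == "translocation")
  if (any(bad_type)) {
    stop("rearrangement type inconsistent with chromosomes at record ",
         which(bad_type)[1], " in ", path)
  }
  if (any(dt$support_reads > dt$total_reads)) {
    stop("support_reads exceeds total_reads in ", path)
  }
  data.frame(chrom1 = chrom1, pos1 = as.integer(dt$end1),
             strand1 = dt$strand1, chrom2 = chrom2,
             pos2 = as.integer(dt$end2), strand2 = dt$strand2,
             sv_type = sv_type,
             support_reads = as.integer(dt$support_reads),
             total_reads = as.integer(dt$total_reads),
             sample_id = sample_id, timepoint = timepoint)
}

#' Write rearrangements as BEDPE
#'
#' Inverse of [read_rearrangements()]: each 1-based breakpoint `pos` becomes
#' the 0-based half-open interval `(pos - 1, pos)`; the type goes in the
#' `name` column.
#'
#' @param rearrangements internal-format data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(rearrangements, path) {
  r <- rearrangements
  if (nrow(r) > 0) {
    o <- order(r$chrom1, r$pos1, r$chrom2, r$pos2)
    r <- r[o, , drop = FALSE]
    out <- data.frame(r$chrom1, r$pos1 - 1L, r$pos1, r$chrom2, r$pos2 - 1L,
                      r$pos2, r$sv_type, 0L, r$strand1, r$strand2,
                      r$support_reads, r$total_reads)
  } else {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' TSV with columns `chrom`, `start`, `end` (1-based inclusive), `major`,
#' `minor`. Segments of one sample/timepoint must not overlap within a
#' chromosome.
#'
#' @param path TSV file.
#' @param sample_id,timepoint labels attached to every record.
#' @return data.frame of segments.
#' @export
read_segments <- function(path, sample_id, timepoint) {
  timepoint <- match.arg(timepoint, .tp_levels)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("chrom", "start", "end", "major", "minor")
  if (!all(need %in% names(dt))) {
    stop("segment file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  dt$chrom <- normalize_chrom(dt$chrom)
  if (any(dt$start > dt$end)) stop("segment with start > end in ", path)
  if (any(dt$major < dt$minor)) stop("segment with major < minor in ", path)
  for (ch in unique(dt$chrom)) {
    s <- dt[dt$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1) {
      ov <- which(s$start[-1] <= s$end[-nrow(s)])
      if (length(ov)) {
        stop(sprintf(
          "overlapping segments on chromosome %s: (%d,%d) and (%d,%d)",
          ch, s$start[ov[1]], s$end[ov[1]], s$start[ov[1] + 1], s$end[ov[1] + 1]))
      }
    }
  }
  dt$sample_id <- sample_id
  dt$timepoint <- timepoint
  dt
}

#' Read sample purity (aberrant cell fraction) table
#'
#' TSV with columns `sample_id`, `timepoint`, `acf`; every `acf` must lie in
#' (0, 1].
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_purity <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("sample_id", "timepoint", "acf")
  if (!all(need %in% names(dt))) {
    stop("purity file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(dt$acf <= 0 | dt$acf > 1)) {
    stop("purity (acf) must lie in (0, 1]; offending sample: ",
         dt$sample_id[which(dt$acf <= 0 | dt$acf > 1)[1]])
  }
  if (!all(dt$timepoint %in% .tp_levels)) {
    stop("timepoint must be one of: ", paste(.tp_levels, collapse = ", "))
  }
  dt
}

#' Write a segments table
#' @param segments data.frame with `chrom`, `start`, `end`, `major`, `minor`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  data.table::fwrite(segments[, c("chrom", "start", "end", "major", "minor")],
                     path, sep = "\t")
  invisible(path)
}

#' Write a context count matrix as TSV (first column = subset label)
#' @param mat matrix from [build_context_matrix()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_context_matrix <- function(mat, path) {
  df <- data.frame(subset = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a context count matrix written by [write_context_matrix()]
#' @param path TSV file.
#' @return integer matrix with 96 named columns.
#' @export
read_context_matrix <- function(path) {
  df <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (ncol(mat) != 96) stop("context matrix must have 96 class columns")
  storage.mode(mat) <- "integer"
  mat
}

#' Write a signature catalog as TSV (first column = signature name)
#' @param catalog processes x 96 probability matrix.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(signature = rownames(catalog), as.data.frame(catalog),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a signature catalog written by [write_catalog()]
#' @param path TSV file.
#' @return processes x 96 probability matrix.
#' @export
read_catalog <- function(path) {
  df <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
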