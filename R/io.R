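# Readers and writers: FASTA/FASTQ via Biostrings-compatible plain formats,
# SVs as BED4+ or VCF 4.2, the k-mer panel as a versioned TSV.

#' Read a FASTA reference
#'
#' @param path FASTA path (plain or gzip).
#' @return named character vector of contig sequences (names truncated at the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write a FASTA reference
#' @param seqs named character vector of contig sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path output path; `.gz` suffix enables gzip.
#' @param ids read identifiers (default `read000001`, ...).
#' @param suffix appended to each id (e.g. `"/1"`).
#' @export
write_fastq <- function(reads, path, ids = NULL, suffix = "") {
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  lines <- character(4L * length(reads))
  lines[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", ids, suffix)
  lines[seq(2L, by = 4L, length.out = length(reads))] <- reads
  lines[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(reads))] <- strrep("I", nchar(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Read SV records from BED or VCF
#'
#' BED4+ is taken as 0-based half-open with column 4 holding
#' `svtype[;id][;seq=...]`. VCF 4.2 positions are converted from 1-based:
#' symbolic ALTs `<DEL>`/`<INV>` use INFO `END` (footprint `[POS, END)`
#' 0-based); a literal ALT longer than REF becomes an insertion at `POS`
#' (0-based) with the shared leading base stripped; a literal REF longer than
#' ALT becomes a deletion.
#'
#' @param path input path.
#' @param format `"BED"`, `"VCF"` or `"auto"` (by extension).
#' @return an [sv_records()] table (with a `genotype` column when the VCF has
#'   genotypes).
#' @export
read_sv_file <- function(path, format = c("auto", "BED", "VCF")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "VCF" else "BED"
  if (format == "BED") .read_sv_bed(path) else .read_sv_vcf(path)
}

.read_sv_bed <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = c("character", "integer", "integer", "character"),
               col.names = c("chrom", "start", "end", "info")),
    error = function(e) stop("malformed BED file ", path, ": ", conditionMessage(e)))
  fields <- strsplit(df$info, ";", fixed = TRUE)
  svtype <- vapply(fields, `[`, character(1), 1)
  id <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 2 && !startsWith(f[2], "seq=")) f[2] else sprintf("sv%04d", i)
  }, character(1))
  seq <- vapply(fields, function(f) {
    s <- grep("^seq=", f, value = TRUE)
    if (length(s)) sub("^seq=", "", s[1]) else ""
  }, character(1))
  ins_noseq <- toupper(svtype) == "INS" & !nzchar(seq)
  if (any(ins_noseq))
    warning("INS records without seq= field: ",
            paste(id[ins_noseq], collapse = ", "),
            " (inserted sequence required unless alignments are supplied)")
  sv_records(id, df$chrom, df$start, df$end, svtype, seq)
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
  out[hit] <- sub(paste0(".*", key, "="), "", m)
  out
}

.read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)
  n <- nrow(fix)
  id <- ifelse(is.na(fix$ID) | fix$ID == ".", sprintf("sv%04d", seq_len(n)), fix$ID)
  svtype <- character(n); start <- integer(n); end <- integer(n)
  ins_seq <- rep("", n)
  for (i in seq_len(n)) {
    alt <- fix$ALT[i]; ref <- fix$REF[i]
    if (grepl("^<", alt)) {
      svtype[i] <- gsub("[<>]", "", alt)
      endfield <- .info_field(fix$INFO[i], "END")
      if (is.na(endfield)) stop("symbolic ALT without INFO END at line for ", id[i])
      start[i] <- pos[i]           # POS is the base before the event
      end[i] <- as.integer(endfield)
      if (svtype[i] == "INS") {
        end[i] <- start[i]
        sq <- .info_field(fix$INFO[i], "SVINSSEQ")
        if (!is.na(sq)) ins_seq[i] <- sq
      }
    } else if (nchar(alt) > nchar(ref)) {
      svtype[i] <- "INS"
      start[i] <- end[i] <- pos[i]  # after the shared leading base
      ins_seq[i] <- substr(alt, nchar(ref) + 1L, nchar(alt))
    } else if (nchar(ref) > nchar(alt)) {
      svtype[i] <- "DEL"
      start[i] <- pos[i]
      end[i] <- pos[i] + nchar(ref) - nchar(alt)
    } else stop("cannot interpret REF/ALT as an SV for record ", id[i])
  }
  svs <- sv_records(id, fix$CHROM, start, end, svtype, ins_seq)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  if (!is.null(gt) && ncol(gt) >= 1) {
    g <- gsub("\\|", "/", gt[, 1])
    g <- ifelse(g %in% c("1/0"), "0/1", g)
    svs$genotype <- ifelse(g %in% GENOTYPES, g, NA_character_)
  }
  svs
}

#' Write SV records as BED4+
#' @param svs an [sv_records()] table.
#' @param path output path.
#' @export
write_sv_bed <- function(svs, path) {
  info <- paste0(svs$svtype, ";", svs$id,
                 ifelse(nzchar(svs$inserted_seq),
                        paste0(";seq=", svs$inserted_seq), ""))
  df <- data.frame(svs$chrom, svs$start, svs$end, info)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write genotype calls as VCF 4.2
#'
#' One record per SV with symbolic ALT, INFO `SVTYPE`/`END` (`SVINSSEQ` for
#' insertions), and FORMAT `GT:PL:NK`: the genotype, phred-scaled genotype
#' likelihoods normalized to the best genotype, and the number of supporting
#' k-mers. Missing calls are emitted as `./.`.
#'
#' @param calls data.frame with `sv_id`, `genotype` and optionally `ll_00`,
#'   `ll_01`, `ll_11`, `n_kmers`.
#' @param svs [sv_records()] table covering the calls.
#' @param ref optional named reference (fills the REF base; `N` otherwise).
#' @param path output path.
#' @param sample_name sample column name.
#' @export
write_genotype_vcf <- function(calls, svs, ref = NULL, path,
                               sample_name = "SAMPLE") {
  svs <- svs[match(calls$sv_id, svs$id), , drop = FALSE]
  pos <- svs$start  # 1-based base before the event == 0-based start
  refbase <- rep("N", nrow(svs))
  if (!is.null(ref)) {
    for (i in seq_len(nrow(svs)))
      refbase[i] <- substr(ref[[svs$chrom[i]]], pos[i], pos[i])
  }
  info <- paste0("SVTYPE=", svs$svtype, ";END=", svs$end,
                 ifelse(svs$svtype == "INS" & nzchar(svs$inserted_seq),
                        paste0(";SVINSSEQ=", svs$inserted_seq), ""))
  has_ll <- all(c("ll_00", "ll_01", "ll_11") %in% names(calls))
  fmt <- if (has_ll) "GT:PL:NK" else "GT"
  gtcol <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- calls$genotype[i]
    if (is.na(g)) {
      gtcol[i] <- if (has_ll) "./.:.:0" else "./."
    } else if (has_ll) {
      ll <- c(calls$ll_00[i], calls$ll_01[i], calls$ll_11[i])
      pl <- round(-10 * (ll - max(ll)) / log(10))
      gtcol[i] <- paste0(g, ":", paste(pl, collapse = ","), ":",
                         calls$n_kmers[i])
    } else {
      gtcol[i] <- g
    }
  }
  header <- c("##fileformat=VCFv4.2",
    "##source=svkmer",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"0-based exclusive end of the SV footprint\">",
    "##INFO=<ID=SVINSSEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods (0/0,0/1,1/1)\">",
    "##FORMAT=<ID=NK,Number=1,Type=Integer,Description=\"Number of supporting k-mers\">",
    paste0("##ALT=<ID=DEL,Description=\"Deletion\">"),
    paste0("##ALT=<ID=INS,Description=\"Insertion\">"),
    paste0("##ALT=<ID=INV,Description=\"Inversion\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- paste(svs$chrom, pos, svs$id, refbase,
                paste0("<", svs$svtype, ">"), ".", "PASS", info, fmt, gtcol,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype calls from a VCF
#'
#' @param path VCF path.
#' @return data.frame `sv_id`, `genotype` (`NA` for `./.`), plus `n_kmers`
#'   when the FORMAT carries NK.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  g <- gsub("\\|", "/", gt[, 1])
  g[g == "1/0"] <- "0/1"
  g[!g %in% GENOTYPES] <- NA_character_
  out <- data.frame(sv_id = fix$ID, genotype = unname(g),
                    stringsAsFactors = FALSE)
  nk <- tryCatch(vcfR::extract.gt(v, element = "NK"), error = function(e) NULL)
  if (!is.null(nk)) out$n_kmers <- suppressWarnings(as.integer(nk[, 1]))
  out
}

PANEL_VERSION <- 1L

#' Write a k-mer panel as TSV
#'
#' Plain (optionally gzipped) tab-separated panel with a versioned header
#' line recording k and the creation parameters; columns `kmer_sequence`,
#' `sv_id`, `role`, `left_neighbor`, `right_neighbor`, `copies_00`,
#' `copies_01`, `copies_11`. Round-trips bit-exactly through [read_panel()].
#'
#' @param panel panel data.frame from [extract_panel()].
#' @param path output path (`.gz` for gzip).
#' @param params optional named list serialized into the header.
#' @export
write_panel <- function(panel, path, params = NULL) {
  k <- attr(panel, "k")
  if (is.null(k)) k <- nchar(panel$kmer[1])
  hdr <- sprintf("#svkmer_panel\tversion=%d\tk=%d", PANEL_VERSION, k)
  if (!is.null(params))
    hdr <- paste(c(hdr, paste0(names(params), "=", unlist(params))),
                 collapse = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(hdr, con)
  df <- data.frame(kmer_sequence = panel$kmer, sv_id = panel$sv_id,
                   role = panel$role,
                   left_neighbor = ifelse(is.na(panel$left_neighbor), ".",
                                          panel$left_neighbor),
                   right_neighbor = ifelse(is.na(panel$right_neighbor), ".",
                                           panel$right_neighbor),
                   copies_00 = panel$copies_00, copies_01 = panel$copies_01,
                   copies_11 = panel$copies_11, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a k-mer panel TSV
#' @param path panel path (plain or `.gz`).
#' @return panel data.frame with attribute `k`.
#' @export
read_panel <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  hdr <- readLines(con, n = 1)
  if (!startsWith(hdr, "#svkmer_panel")) stop("not a svkmer panel: ", path)
  fields <- strsplit(hdr, "\t")[[1]]
  k <- as.integer(sub("k=", "", grep("^k=", fields, value = TRUE)[1]))
  df <- read.table(con, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(rep("character", 5), rep("numeric", 3)))
  panel <- data.frame(kmer = df$kmer_sequence, sv_id = df$sv_id,
                      role = df$role,
                      left_neighbor = ifelse(df$left_neighbor == ".",
                                             NA_character_, df$left_neighbor),
                      right_neighbor = ifelse(df$right_neighbor == ".",
                                              NA_character_, df$right_neighbor),
                      copies_00 = df$copies_00, copies_01 = df$copies_01,
                      copies_11 = df$copies_11, stringsAsFactors = FALSE)
  attr(panel, "k") <- k
  panel
}
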