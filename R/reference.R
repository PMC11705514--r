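#' Parse tRNAscan-SE 2.0 tabular output
#'
#' Reads the standard `.out` table (columns: sequence name, tRNA#, begin,
#' end, isotype, anticodon, intron begin/end, score, note). Genomic
#' coordinates are 1-based inclusive; minus-strand genes are recognized by
#' begin > end and their stored precursor sequence is the
#' reverse-complemented (sense) strand when a genome is supplied. Intron
#' bounds of 0,0 mean no intron; non-zero bounds are converted to
#' sequence-local 1-based coordinates. Rows flagged `pseudo` or truncated
#' in the note column lose the high-confidence flag, consuming the
#' high-confidence filter the gene list was passed through.
#'
#' @param path Path to the tRNAscan-SE `.out` file.
#' @param genome Optional named [Biostrings::DNAStringSet] (or named
#'   character vector) of the genome; when given, precursor sequences are
#'   extracted.
#' @param high_confidence_only Drop rows without the high-confidence flag.
#' @return Data.frame with columns `gene_id`, `seqname`, `begin`, `end`,
#'   `strand`, `isotype`, `anticodon`, `intron_start`, `intron_end`
#'   (sequence-local, NA if none), `score`, `note`, `high_confidence` and
#'   (with a genome) `sequence`.
#' @export
parse_trnascan <- function(path, genome = NULL, high_confidence_only = FALSE) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^(Sequence|Name|-----)", lines) & nzchar(trimws(lines))]
  rows <- list()
  counter <- new.env(parent = emptyenv())
  for (k in seq_along(body)) {
    fields <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(fields) < 9L) {
      stop("malformed tRNAscan-SE row at data line ", k, ": '",
           body[k], "'")
    }
    begin <- suppressWarnings(as.integer(fields[3]))
    end <- suppressWarnings(as.integer(fields[4]))
    ib <- suppressWarnings(as.integer(fields[7]))
    ie <- suppressWarnings(as.integer(fields[8]))
    score <- suppressWarnings(as.numeric(fields[9]))
    if (anyNA(c(begin, end, ib, ie, score))) {
      stop("malformed numeric field in tRNAscan-SE row at data line ", k,
           ": '", body[k], "'")
    }
    note <- if (length(fields) > 9L) paste(fields[-(1:9)], collapse = " ")
            else ""
    strand <- if (begin <= end) "+" else "-"
    glen <- abs(end - begin) + 1L
    if (ib == 0L && ie == 0L) {
      istart <- NA_integer_; iend <- NA_integer_
    } else {
      # genomic -> sequence-local (transcribed orientation)
      if (strand == "+") {
        istart <- ib - begin + 1L
        iend <- ie - begin + 1L
      } else {
        istart <- begin - ib + 1L
        iend <- begin - ie + 1L
      }
      if (istart > iend) { tmp <- istart; istart <- iend; iend <- tmp }
      if (istart < 1L || iend > glen) {
        stop("intron span outside gene bounds at data line ", k)
      }
    }
    isotype <- fields[5]
    anticodon <- fields[6]
    key <- paste(isotype, anticodon, sep = "-")
    counter[[key]] <- if (is.null(counter[[key]])) 1L else counter[[key]] + 1L
    gene_id <- sprintf("%s-%s-%d-1", isotype, anticodon, counter[[key]])
    rows[[k]] <- data.frame(
      gene_id = gene_id, seqname = fields[1], begin = begin, end = end,
      strand = strand, isotype = isotype, anticodon = anticodon,
      intron_start = istart, intron_end = iend, score = score, note = note,
      high_confidence = !grepl("pseudo|trunc", note, ignore.case = TRUE),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(genome)) {
    gseq <- stats::setNames(as.character(genome), names(genome))
    out$sequence <- vapply(seq_len(nrow(out)), function(i) {
      if (!out$seqname[i] %in% names(gseq)) {
        stop("sequence '", out$seqname[i], "' not found in genome")
      }
      chrom <- gseq[[out$seqname[i]]]
      lo <- min(out$begin[i], out$end[i])
      hi <- max(out$begin[i], out$end[i])
      s <- substr(chrom, lo, hi)
      if (out$strand[i] == "-") s <- .revcomp(s)
      s
    }, "")
  }
  if (high_confidence_only) out <- out[out$high_confidence, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Mature tRNA sequence from a gene
#'
#' Removes the intron (if any) from the precursor body and appends the
#' post-transcriptionally added 3' CCA. Mature length is therefore
#' precursor length minus intron length plus 3. No other maturation step
#' (e.g. the histidine 5'-G addition) is applied.
#'
#' @param sequence Precursor (gene-body) sequence string.
#' @param intron_start,intron_end 1-based inclusive intron span in the
#'   sequence, or `NA` for intronless genes.
#' @return Mature sequence string ending in `CCA`.
#' @export
mature_sequence <- function(sequence, intron_start = NA, intron_end = NA) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.na(intron_start)) {
    stopifnot(!is.na(intron_end), intron_start >= 1,
              intron_end <= nchar(sequence), intron_start <= intron_end)
    sequence <- paste0(substr(sequence, 1L, intron_start - 1L),
                       substr(sequence, intron_end + 1L, nchar(sequence)))
  }
  paste0(sequence, "CCA")
}

#' Remove exact duplicate precursor sequences
#'
#' Collapses genes with byte-identical sequences, keeping the first id
#' seen; duplicate ids are recorded so isodecoders (sequences differing
#' by even one nucleotide) are never merged.
#'
#' @param genes Data.frame with columns `gene_id` and `sequence`.
#' @return List with `unique` (the deduplicated data.frame) and
#'   `duplicates` (data.frame `gene_id`, `kept_as`).
#' @export
dedupe_pre <- function(genes) {
  stopifnot(all(c("gene_id", "sequence") %in% names(genes)))
  first <- !duplicated(genes$sequence)
  kept <- genes[first, , drop = FALSE]
  dup <- genes[!first, , drop = FALSE]
  kept_as <- kept$gene_id[match(dup$sequence, kept$sequence)]
  list(
    unique = kept,
    duplicates = data.frame(gene_id = dup$gene_id, kept_as = kept_as,
                            stringsAsFactors = FALSE)
  )
}

#' Expression calls from a TPM table
#'
#' A transcript is expressed in a condition when its mean TPM over that
#' condition's replicates is strictly greater than 1 (TPM of exactly 1 is
#' called not expressed). Condition-exclusive sets are transcripts
#' expressed in exactly one condition.
#'
#' @param tpm Data.frame with columns `transcript`, `sample`, `condition`,
#'   `tpm` (all TPM >= 0).
#' @param threshold Expression threshold on mean TPM (strict >), default 1.
#' @return List with `calls` (transcript, condition, mean_tpm, status) and
#'   `exclusive` (named list of transcript ids per condition).
#' @export
expression_calls <- function(tpm, threshold = 1) {
  need <- c("transcript", "sample", "condition", "tpm")
  if (!all(need %in% names(tpm))) {
    stop("tpm table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tpm$tpm < 0)) stop("negative TPM values are invalid")
  agg <- stats::aggregate(tpm ~ transcript + condition, data = tpm, FUN = mean)
  names(agg)[names(agg) == "tpm"] <- "mean_tpm"
  agg$status <- ifelse(agg$mean_tpm > threshold, "expressed", "not expressed")
  conds <- unique(agg$condition)
  exclusive <- lapply(conds, function(cd) {
    expressed_here <- agg$transcript[agg$condition == cd &
                                       agg$status == "expressed"]
    expressed_elsewhere <- unique(
      agg$transcript[agg$condition != cd & agg$status == "expressed"])
    sort(setdiff(expressed_here, expressed_elsewhere))
  })
  names(exclusive) <- conds
  list(calls = agg[order(agg$transcript, agg$condition), , drop = FALSE],
       exclusive = exclusive)
}

#' Write mature and precursor tRNA FASTA reference files
#'
#' Builds the precursor set (deduplicated gene bodies, unaltered) and the
#' mature set (intron removed, CCA appended) and writes both as FASTA.
#'
#' @param genes Data.frame from [parse_trnascan()] (needs `gene_id`,
#'   `sequence`, `intron_start`, `intron_end`).
#' @param dir Output directory.
#' @return List with paths `mature`, `pre`, `dedupe_report` and the
#'   in-memory tables.
#' @export
build_reference <- function(genes, dir) {
  stopifnot(all(c("gene_id", "sequence") %in% names(genes)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!"intron_start" %in% names(genes)) genes$intron_start <- NA_integer_
  if (!"intron_end" %in% names(genes)) genes$intron_end <- NA_integer_
  dd <- dedupe_pre(genes)
  pre <- dd$unique
  mature <- pre
  mature$sequence <- vapply(seq_len(nrow(pre)), function(i) {
    mature_sequence(pre$sequence[i],
                    intron_start = pre$intron_start[i],
                    intron_end = pre$intron_end[i])
  }, "")
  mature_path <- file.path(dir, "mature.fasta")
  pre_path <- file.path(dir, "pre.fasta")
  .write_fasta(stats::setNames(mature$sequence, mature$gene_id), mature_path)
  .write_fasta(stats::setNames(pre$sequence, pre$gene_id), pre_path)
  report_path <- file.path(dir, "dedupe_report.tsv")
  utils::write.table(dd$duplicates, report_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  list(mature = mature_path, pre = pre_path, dedupe_report = report_path,
       mature_table = mature, pre_table = pre, duplicates = dd$duplicates)
}

.write_fasta <- function(named_seqs, path) {
  set <- Biostrings::DNAStringSet(named_seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))  # id = first header token
  stats::setNames(as.character(set), ids)
}
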