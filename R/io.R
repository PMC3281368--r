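## Readers and writers for the pipeline's interchange formats: FASTA
## (Biostrings), GFF3 repeat annotations (rtracklayer/GenomicRanges),
## PHYLIP square distance matrices, newick trees (ape), and the plain-text
## truth/config/group tables.

#' Read a FASTA file of spacer sequences
#'
#' Preserves record order and ids, uppercases sequences, and validates the
#' alphabet.  Duplicate ids and non-IUPAC characters (reported with their
#' position) are errors.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences (empty for an
#'   empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA: ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- which(!seq_to_chars(seqs[i]) %in% IUPAC_LETTERS)
    if (length(bad))
      stop("non-IUPAC character '", substr(seqs[i], bad[1], bad[1]),
           "' at position ", bad[1], " of record ", ids[i])
  }
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA wrapped at 60 columns
#'
#' @param seqs Named character vector (gaps allowed, for alignments).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write repeat annotations as GFF3
#'
#' One `repeat_region` feature per array and one `repeat_unit` child per
#' unit.  Internal 0-based half-open coordinates are converted to the
#' 1-based inclusive GFF3 convention.
#'
#' @param units_by_record List of `repeat_units` data.frames (one per
#'   record, as from [extract_units()]).
#' @param path Output GFF3 file.
#' @return The path, invisibly.
#' @export
write_units_gff3 <- function(units_by_record, path) {
  grs <- list()
  for (u in units_by_record) {
    if (!nrow(u)) next
    rid <- u$parent_id[1]
    aid <- paste0("array_", rid)
    region <- GenomicRanges::GRanges(
      seqnames = rid,
      ranges = IRanges::IRanges(start = min(u$start) + 1L, end = max(u$end)),
      type = "repeat_region", ID = aid, Name = aid)
    kids <- GenomicRanges::GRanges(
      seqnames = rid,
      ranges = IRanges::IRanges(start = u$start + 1L, end = u$end),
      type = "repeat_unit", ID = u$name, Name = u$name)
    S4Vectors::mcols(kids)$Parent <- aid
    grs[[length(grs) + 1L]] <- region
    grs[[length(grs) + 1L]] <- kids
  }
  if (!length(grs)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read repeat-unit annotations from GFF3
#'
#' @param path GFF3 file written by [write_units_gff3()] (or compatible).
#' @return List of `repeat_units`-style data.frames keyed by record id
#'   (coordinates converted back to 0-based half-open).
#' @export
read_units_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "repeat_unit"]
  if (!length(gr)) return(list())
  df <- data.frame(
    parent_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = gr$Name,
    stringsAsFactors = FALSE)
  out <- split(df, df$parent_id)
  lapply(out, function(u) {
    u <- u[order(u$start), , drop = FALSE]
    u$index <- seq_len(nrow(u))
    rownames(u) <- NULL
    u
  })
}

#' Write a distance matrix in PHYLIP square format
#' @param dmatrix Labelled symmetric matrix.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_phylip <- function(dmatrix, path) {
  if (inherits(dmatrix, "dist")) dmatrix <- as.matrix(dmatrix)
  labs <- rownames(dmatrix)
  lines <- c(sprintf("%5d", nrow(dmatrix)),
             vapply(seq_len(nrow(dmatrix)), function(i) {
               paste0(formatC(labs[i], width = -12L),
                      paste(sprintf("%.6f", dmatrix[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#' @param path File written by [write_phylip()] (or compatible).
#' @return Labelled symmetric matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    labs[i] <- parts[1]
    m[i, ] <- as.numeric(parts[-1])
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Write the ground-truth unit table of a synthetic dataset
#' @param dataset A `sim_dataset`.
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_truth <- function(dataset, path) {
  utils::write.table(dataset$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a group assignment as TSV
#' @param assignment A `group_assignment`.
#' @param path Output TSV (units with their group id, "ungrouped" for NA).
#' @return The path, invisibly.
#' @export
write_groups <- function(assignment, path) {
  df <- assignment$assignment
  df$group <- ifelse(is.na(df$group), "ungrouped", as.character(df$group))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a simulation config as key=value text
#' @param config A `sim_config`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  ser <- function(x) {
    if (is.list(x)) paste(vapply(x, function(v) paste(v, collapse = ","),
                                 character(1)), collapse = "|")
    else paste(x, collapse = ",")
  }
  keys <- names(config)
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    paste0(k, "=", if (is.null(v)) "" else ser(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation config written by [write_config()]
#' @param path Key=value file.
#' @return A `sim_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- p[1]
    val <- if (length(p) > 1L) paste(p[-1], collapse = "=") else ""
    out[[key]] <- val
  }
  ## "NA" entries (e.g. unset group lengths) coerce to NA by design
  num <- function(x) if (nzchar(x))
    suppressWarnings(as.numeric(strsplit(x, ",")[[1]])) else NULL
  chr <- function(x) strsplit(x, ",")[[1]]
  pattern <- if (grepl("|", out$unit_pattern, fixed = TRUE) ||
                 grepl("^[0-9]", out$unit_pattern)) {
    lapply(strsplit(out$unit_pattern, "|", fixed = TRUE)[[1]],
           function(s) as.integer(strsplit(s, ",")[[1]]))
  } else out$unit_pattern
  gl <- num(out$group_lengths)
  sim_config(seed = as.integer(out$seed),
             species = chr(out$species),
             units_per_species = as.integer(num(out$units_per_species)),
             n_groups = as.integer(out$n_groups),
             unit_pattern = pattern,
             unit_length_range = as.integer(num(out$unit_length_range)),
             group_lengths = if (length(gl)) as.integer(gl) else NULL,
             within_group_divergence = as.numeric(out$within_group_divergence),
             between_group_divergence = as.numeric(out$between_group_divergence),
             motif5 = out$motif5, motif3 = out$motif3,
             flank_lengths = as.integer(num(out$flank_lengths)),
             background_divergence = as.numeric(out$background_divergence),
             species_scale = num(out$species_scale),
             indel_rate = as.numeric(out$indel_rate),
             isolines_per_species = as.integer(out$isolines_per_species),
             within_species_divergence = as.numeric(out$within_species_divergence))
}

#' Write a synthetic dataset (FASTA + truth sidecar + config)
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisible list of the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "spacers.fasta")
  tr <- file.path(dir, "truth.tsv")
  cf <- file.path(dir, "config.txt")
  write_fasta(dataset$records, fa)
  write_truth(dataset, tr)
  write_config(dataset$config, cf)
  invisible(list(fasta = fa, truth = tr, config = cf))
}
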