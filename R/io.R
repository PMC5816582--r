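# Readers and writers for the on-disk formats the pipeline touches.
# All readers validate strictly and fail with the offending column or row.

.SPOT_COLS <- c("array_id", "probe_id", "fg_ch1", "bg_ch1", "fg_ch2",
                "bg_ch2", "flagged")
.DESIGN_COLS <- c("array_id", "dye", "sample_id", "species", "water",
                  "temperature", "date", "replicate")
.OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

.check_spots <- function(spots, origin = "spot table") {
  int_cols <- c("fg_ch1", "bg_ch1", "fg_ch2", "bg_ch2")
  for (col in int_cols) {
    v <- spots[[col]]
    if (any(!is.finite(v))) {
      stop_fmt("%s: non-finite %s at row %d", origin, col,
               which(!is.finite(v))[1])
    }
    if (any(v < 0)) {
      stop_fmt("%s: negative intensity in %s at row %d", origin, col,
               which(v < 0)[1])
    }
  }
  key <- paste(spots$array_id, spots$probe_id)
  if (anyDuplicated(key)) {
    stop_fmt("%s: duplicate (array_id, probe_id): %s", origin,
             key[anyDuplicated(key)])
  }
  spots
}

#' Read a spot-level intensity table
#'
#' Supports two dialects: a plain 7-column TSV
#' (`array_id probe_id fg_ch1 bg_ch1 fg_ch2 bg_ch2 flagged`) and a minimal
#' GenePix GPR (Axon Text File) subset from which only the probe identifier,
#' the per-channel median foreground/background and `Flags` are consumed.
#' Channels are positional: for GPR, the 532 nm columns map to `ch1` and the
#' 635 nm columns to `ch2`; which dye/sample sits in which channel is the
#' design table's business, not the spot file's.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"gpr"`.
#' @param array_id array identifier for GPR files (which carry none);
#'   defaults to the file basename without extension.
#' @return A data.frame of spot records with the 7 canonical columns;
#'   `flagged` is logical (GPR rows with `Flags < 0` are flagged).
#' @export
read_spot_table <- function(path, dialect = c("tsv", "gpr"),
                            array_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("spot table not found: %s", path)
  if (file.size(path) == 0) stop_fmt("spot table is empty: %s", path)
  if (dialect == "tsv") {
    df <- .read_tsv(path)
    missing <- setdiff(.SPOT_COLS, names(df))
    if (length(missing)) {
      stop_fmt("spot table %s: missing column(s): %s", path,
               paste(missing, collapse = ", "))
    }
    if (nrow(df) == 0) stop_fmt("spot table has no data rows: %s", path)
    spots <- data.frame(
      array_id = as.character(df$array_id),
      probe_id = as.character(df$probe_id),
      fg_ch1 = as.numeric(df$fg_ch1), bg_ch1 = as.numeric(df$bg_ch1),
      fg_ch2 = as.numeric(df$fg_ch2), bg_ch2 = as.numeric(df$bg_ch2),
      flagged = as.logical(as.integer(df$flagged)),
      stringsAsFactors = FALSE
    )
  } else {
    spots <- .read_gpr(path, array_id = array_id)
  }
  .check_spots(spots, origin = path)
}

# Minimal ATF/GPR reader: ATF header, "nHeaders nCols" line, nHeaders
# key=value records, then a tab-separated column block.
.read_gpr <- function(path, array_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !grepl("^ATF", lines[1])) {
    stop_fmt("not an ATF/GPR file: %s", path)
  }
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2]),
                                                 "\\s+")[[1]]))
  if (length(counts) < 1 || is.na(counts[1])) {
    stop_fmt("malformed ATF header count line: %s", path)
  }
  n_header <- counts[1]
  body <- lines[-seq_len(2 + n_header)]
  if (length(body) < 2) stop_fmt("GPR file has no data block: %s", path)
  strip <- function(x) gsub('^"|"$', "", x)
  header <- strip(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  need <- c("F532 Median", "B532 Median", "F635 Median", "B635 Median",
            "Flags")
  missing <- setdiff(need, header)
  if (length(missing)) {
    stop_fmt("GPR %s: missing column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  id_col <- if ("ID" %in% header) "ID" else if ("Name" %in% header) "Name"
            else stop_fmt("GPR %s: missing column(s): ID/Name", path)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  rows <- rows[lengths(rows) >= length(header)]
  get <- function(col) vapply(rows, function(r) strip(r[match(col, header)]),
                              character(1))
  if (is.null(array_id)) {
    array_id <- tools::file_path_sans_ext(basename(path))
  }
  data.frame(
    array_id = array_id,
    probe_id = get(id_col),
    fg_ch1 = as.numeric(get("F532 Median")),
    bg_ch1 = as.numeric(get("B532 Median")),
    fg_ch2 = as.numeric(get("F635 Median")),
    bg_ch2 = as.numeric(get("B635 Median")),
    flagged = as.numeric(get("Flags")) < 0,
    stringsAsFactors = FALSE
  )
}

#' Write a spot table in the TSV dialect
#'
#' Round-trips with [read_spot_table()]: all fields are preserved exactly.
#'
#' @param spots data.frame of spot records.
#' @param path output path.
#' @export
write_spot_table <- function(spots, path) {
  out <- spots[, .SPOT_COLS]
  out$flagged <- as.integer(out$flagged)
  .write_tsv(out, path)
}

#' Read and validate an experiment design table
#'
#' The design maps each (array, channel) to a labelled sample and its four
#' factor levels.  Every array must have exactly two rows, one per channel
#' (`ch1`, `ch2`); factor levels are validated against the canonical sets.
#'
#' @param path path to an 8-column TSV (`array_id dye sample_id species
#'   water temperature date replicate`).
#' @return A validated data.frame of design rows.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop_fmt("design table not found: %s", path)
  df <- .read_tsv(path)
  missing <- setdiff(.DESIGN_COLS, names(df))
  if (length(missing)) {
    stop_fmt("design table %s: missing column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  df$replicate <- as.integer(df$replicate)
  validate_design(df)
}

#' Validate a design table held in memory
#'
#' @param design data.frame with the 8 design columns.
#' @return The design, invisibly checked (dye set, per-array row counts,
#'   factor levels).
#' @export
validate_design <- function(design) {
  if (!all(design$dye %in% .DYES)) {
    stop_fmt("design error: dye values must be in {%s}",
             paste(.DYES, collapse = ", "))
  }
  key <- paste(design$array_id, design$dye)
  if (anyDuplicated(key)) {
    stop_fmt("design error: duplicate (array_id, dye): %s",
             key[anyDuplicated(key)])
  }
  counts <- table(design$array_id)
  bad <- names(counts)[counts != 2]
  if (length(bad)) {
    stop_fmt("design error: array(s) without exactly 2 rows: %s",
             paste(bad, collapse = ", "))
  }
  for (f in names(.FACTORS)) {
    extra <- setdiff(unique(design[[f]]), .FACTORS[[f]])
    if (length(extra)) {
      stop_fmt("design error: unknown %s level(s): %s", f,
               paste(extra, collapse = ", "))
    }
  }
  design
}

#' Identify dye-swap array pairs
#'
#' Two arrays form a dye-swap pair when they carry the same two samples with
#' the channel assignment exchanged.
#'
#' @param design validated design table.
#' @return data.frame with columns `pair_id`, `array_1`, `array_2` (one row
#'   per pair; arrays without a swap partner are omitted).
#' @export
dye_swap_pairs <- function(design) {
  design <- validate_design(design)
  per_array <- split(design, design$array_id)
  sig <- vapply(per_array, function(d) {
    d <- d[order(d$dye), ]
    paste(sort(d$sample_id), collapse = "|")
  }, character(1))
  ord <- vapply(per_array, function(d) {
    d <- d[order(d$dye), ]
    paste(d$sample_id, collapse = ">")
  }, character(1))
  pairs <- list()
  for (s in unique(sig)) {
    arrays <- names(sig)[sig == s]
    if (length(arrays) < 2) next
    # swap partners carry the same sample set with channel order exchanged
    o <- ord[arrays]
    side1 <- arrays[o == o[1]]
    side2 <- arrays[o != o[1]]
    for (k in seq_len(min(length(side1), length(side2)))) {
      pairs[[length(pairs) + 1]] <- c(side1[k], side2[k])
    }
  }
  if (!length(pairs)) {
    return(data.frame(pair_id = integer(0), array_1 = character(0),
                      array_2 = character(0)))
  }
  m <- do.call(rbind, pairs)
  data.frame(pair_id = seq_len(nrow(m)), array_1 = m[, 1], array_2 = m[, 2],
             stringsAsFactors = FALSE)
}

#' Read a BLAST tabular (outfmt 6) alignment file
#'
#' Column semantics are fixed to the NCBI defaults; the first column is the
#' probe (query) id, the second the transcript (subject) id.
#'
#' @param path path to a 12-column tab-separated file without header.
#' @param species_db label for the transcriptome database the probes were
#'   aligned against (e.g. `"Ag"` or `"Sn"`).
#' @return data.frame of alignment hits with standard outfmt-6 names plus
#'   `species_db`.
#' @export
read_alignment_table <- function(path, species_db) {
  if (!file.exists(path)) stop_fmt("alignment table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    hits <- as.data.frame(setNames(rep(list(character(0)), 12),
                                   .OUTFMT6_COLS))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 12)
    if (length(short)) {
      stop_fmt("alignment table %s: line %d has %d columns (12 required)",
               path, short[1], lengths(fields)[short[1]])
    }
    m <- t(vapply(fields, function(f) f[1:12], character(12)))
    hits <- as.data.frame(m, stringsAsFactors = FALSE)
    names(hits) <- .OUTFMT6_COLS
  }
  num_cols <- setdiff(.OUTFMT6_COLS, c("qseqid", "sseqid"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    if (any(is.na(v) & !is.na(hits[[col]]))) {
      stop_fmt("alignment table %s: unparsable %s at line %d", path, col,
               which(is.na(v))[1])
    }
    hits[[col]] <- v
  }
  if (any(hits$length < 1)) {
    stop_fmt("alignment table %s: alignment length < 1 at line %d", path,
             which(hits$length < 1)[1])
  }
  if (any(hits$evalue < 0)) {
    stop_fmt("alignment table %s: negative e-value at line %d", path,
             which(hits$evalue < 0)[1])
  }
  hits$species_db <- species_db
  hits
}

#' Read a probe annotation map (categories + lengths)
#'
#' @param go_path 2-column TSV mapping `probe_id` to a category id; a header
#'   line `probe_id<TAB>category` is recognised and skipped; duplicate
#'   (probe, category) pairs are stored once.
#' @param fasta_path FASTA file of probe sequences; probe length is the
#'   ungapped sequence length.  Probes present in the category map but
#'   absent from the FASTA are dropped with a warning.
#' @return An object of class `annotation_map`: a list with `categories`
#'   (data.frame `probe_id`, `category`) and `lengths` (named integer
#'   vector over all FASTA probes).
#' @export
read_annotation_map <- function(go_path, fasta_path) {
  if (!file.exists(go_path)) stop_fmt("annotation map not found: %s", go_path)
  if (!file.exists(fasta_path)) stop_fmt("FASTA not found: %s", fasta_path)
  if (file.size(fasta_path) == 0) stop_fmt("empty FASTA: %s", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop_fmt("empty FASTA: %s", fasta_path)
  lens <- Biostrings::width(seqs)
  names(lens) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)

  lines <- readLines(go_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[1]), "probe_id\tcategory")) {
    lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    stop_fmt("annotation map %s: line %d has < 2 columns", go_path, bad[1])
  }
  cats <- data.frame(
    probe_id = vapply(fields, `[`, character(1), 1),
    category = vapply(fields, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(cats$category))) {
    stop_fmt("annotation map %s: empty category id at line %d", go_path,
             which(!nzchar(cats$category))[1])
  }
  cats <- unique(cats)
  unknown <- setdiff(cats$probe_id, names(lens))
  if (length(unknown)) {
    warn_fmt("%d probe(s) in the category map are absent from the FASTA and were dropped (e.g. %s)",
             length(unknown), unknown[1])
    cats <- cats[cats$probe_id %in% names(lens), ]
  }
  annotation_map(cats, lens)
}

#' Construct an annotation map in memory
#'
#' @param categories data.frame with `probe_id` and `category`.
#' @param lengths named integer vector of probe lengths (bp, >= 1).
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(categories, lengths) {
  if (any(lengths < 1)) stop_fmt("probe lengths must be >= 1")
  if (is.null(names(lengths))) stop_fmt("lengths must be named by probe id")
  structure(list(categories = unique(categories[, c("probe_id", "category")]),
                 lengths = lengths),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d probes with lengths, %d (probe, category) pairs, %d categories\n",
              length(x$lengths), nrow(x$categories),
              length(unique(x$categories$category))))
  invisible(x)
}

#' Write probe sequences as FASTA
#'
#' Generates random nucleotide sequences of the requested lengths; used by
#' the simulator so that annotation fixtures can flow through the same
#' FASTA reader as real data.
#'
#' @param lengths named integer vector (names become FASTA ids).
#' @param path output path.
#' @export
write_probe_fasta <- function(lengths, path) {
  seqs <- vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(lengths)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
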