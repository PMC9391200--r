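# Reading, validating, QC-filtering and deduplicating peptide repertoires;
# background compositions; HLA allele sequences and cleft residues.

#' Read a peptide table
#'
#' Reads a delimited text file of mass-spectrometry peptide identifications
#' into a data frame of peptide records. The sequence column is mandatory;
#' Mascot ion score, delta mass (ppm) and source-gene expression (TPM) are
#' optional numeric columns. Sequences are uppercased; rows containing
#' non-canonical residue letters or unparseable numeric cells are excluded
#' and reported in the `rejected` attribute.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param column_map Named character vector mapping the internal field names
#'   `sequence`, `allotype`, `ion_score`, `delta_mass_ppm`, `source_tpm` to
#'   column names in the file. Only `sequence` is required; fields absent
#'   from the map and from the file header are left unset (`NA`).
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @return A data.frame with columns `sequence`, `allotype`, `ion_score`,
#'   `delta_mass_ppm`, `source_tpm`, `row` (1-based input row number), with
#'   attribute `rejected`: a data.frame of excluded rows and reasons.
#' @export
read_peptide_table <- function(path,
                               column_map = c(sequence = "sequence"),
                               delim = NULL) {
  if (!file.exists(path)) stop("peptide table not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  fields <- c("sequence", "allotype", "ion_score", "delta_mass_ppm",
              "source_tpm")
  cmap <- column_map
  # default: a file column named exactly like the internal field
  for (f in fields) {
    if (!f %in% names(cmap) && f %in% names(raw)) cmap[f] <- f
  }
  if (!"sequence" %in% names(cmap) || !cmap[["sequence"]] %in% names(raw)) {
    stop("no peptide sequence column (looked for '",
         if ("sequence" %in% names(cmap)) cmap[["sequence"]] else "sequence",
         "')", call. = FALSE)
  }
  n <- nrow(raw)
  seqs <- toupper(trimws(raw[[cmap[["sequence"]]]]))
  get_num <- function(field) {
    if (field %in% names(cmap) && cmap[[field]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[cmap[[field]]]]))
    } else {
      rep(NA_real_, n)
    }
  }
  has_num <- function(field) {
    field %in% names(cmap) && cmap[[field]] %in% names(raw)
  }
  allo <- if ("allotype" %in% names(cmap) && cmap[["allotype"]] %in% names(raw)) {
    as.character(raw[[cmap[["allotype"]]]])
  } else {
    rep(NA_character_, n)
  }
  out <- data.frame(
    sequence = seqs,
    allotype = allo,
    ion_score = get_num("ion_score"),
    delta_mass_ppm = get_num("delta_mass_ppm"),
    source_tpm = get_num("source_tpm"),
    row = seq_len(n),
    stringsAsFactors = FALSE
  )

  reasons <- character(0)
  bad_rows <- integer(0)
  # alphabet rule: reject, never silently fix
  bad_chr <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                    out$sequence)
  for (i in which(bad_chr)) {
    offending <- setdiff(strsplit(out$sequence[i], "")[[1]], AA_ALPHABET)
    bad_rows <- c(bad_rows, i)
    reasons <- c(reasons, paste0("non-canonical residue ",
                                 paste(unique(offending), collapse = "")))
  }
  # numeric cells present in the file but unparseable
  for (field in c("ion_score", "delta_mass_ppm", "source_tpm")) {
    if (!has_num(field)) next
    cell <- trimws(raw[[cmap[[field]]]])
    bad_num <- which(is.na(out[[field]]) & !(cell == "" | is.na(cell) |
                                               toupper(cell) == "NA"))
    for (i in bad_num) {
      bad_rows <- c(bad_rows, i)
      reasons <- c(reasons, paste0("unparseable ", field, " '", cell[i], "'"))
    }
  }
  rejected <- data.frame(row = bad_rows,
                         sequence = out$sequence[bad_rows],
                         reason = reasons, stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(n), unique(bad_rows))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' QC thresholds for peptide filtering
#'
#' Thresholds are inclusive: a Mascot ion score exactly at the minimum and a
#' source-gene TPM exactly at the minimum both pass. Records missing an
#' optional field pass that check unless the corresponding `require_*` flag
#' is set. Delta-mass filtering is off by default (`max_delta_mass_ppm =
#' Inf`); no published cutoff exists.
#'
#' @param min_ion_score Minimum Mascot ion score (default 25).
#' @param min_tpm Minimum source-gene expression in TPM (default 0.3).
#' @param length_range Inclusive peptide length range (default 8--13).
#' @param max_delta_mass_ppm Maximum absolute delta mass in ppm (default Inf).
#' @param require_ion_score,require_tpm,require_delta_mass If TRUE, records
#'   missing the field are rejected instead of passed.
#' @return An object of class `pc_qc_thresholds`.
#' @export
qc_thresholds <- function(min_ion_score = 25, min_tpm = 0.3,
                          length_range = c(8L, 13L),
                          max_delta_mass_ppm = Inf,
                          require_ion_score = FALSE,
                          require_tpm = FALSE,
                          require_delta_mass = FALSE) {
  stopifnot(min_ion_score >= 0, length(length_range) == 2L,
            length_range[1] <= length_range[2])
  structure(list(min_ion_score = min_ion_score, min_tpm = min_tpm,
                 length_range = as.integer(length_range),
                 max_delta_mass_ppm = max_delta_mass_ppm,
                 require_ion_score = require_ion_score,
                 require_tpm = require_tpm,
                 require_delta_mass = require_delta_mass),
            class = "pc_qc_thresholds")
}

#' Construct a peptide repertoire
#'
#' A repertoire is a deduplicated set of peptide sequences for one
#' allotype/variant, the unit of all frequency analyses.
#'
#' @param sequences Character vector of uppercase canonical peptide sequences.
#' @param name Repertoire label (e.g. the HLA variant).
#' @param length_range Inclusive allowed length range.
#' @return Object of class `pc_repertoire` with elements `name`, `peptides`
#'   (character vector, unique), `length_range`.
#' @export
repertoire <- function(sequences, name = "repertoire",
                       length_range = c(8L, 13L)) {
  sequences <- as.character(sequences)
  if (anyDuplicated(sequences)) sequences <- unique(sequences)
  if (length(sequences) > 0) {
    ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                sequences)
    if (!all(ok)) {
      stop("non-canonical residues in sequences: ",
           paste(utils::head(sequences[!ok], 3), collapse = ", "),
           call. = FALSE)
    }
    len <- nchar(sequences)
    if (any(len < length_range[1] | len > length_range[2])) {
      stop("peptide length outside [", length_range[1], ", ",
           length_range[2], "]", call. = FALSE)
    }
  }
  structure(list(name = name, peptides = sequences,
                 length_range = as.integer(length_range)),
            class = "pc_repertoire")
}

#' @export
length.pc_repertoire <- function(x) length(x$peptides)

#' @export
print.pc_repertoire <- function(x, ...) {
  cat("<pc_repertoire> ", x$name, ": ", length(x$peptides),
      " unique peptides, lengths ", x$length_range[1], "-",
      x$length_range[2], "\n", sep = "")
  invisible(x)
}

#' QC-filter peptide records into a repertoire
#'
#' Applies the quality-control thresholds (ion score, source-gene TPM,
#' length window, optional delta-mass window) to parsed peptide records,
#' deduplicates by exact sequence (first occurrence kept), and returns the
#' retained repertoire together with a rejection report counting failures
#' by reason. A record failing several checks is counted once, under the
#' first failed check in the order: length, ion_score, delta_mass, tpm.
#'
#' @param records Data frame as returned by [read_peptide_table()], or a
#'   character vector of sequences.
#' @param thresholds A [qc_thresholds()] object.
#' @param name Name for the resulting repertoire.
#' @return List with `repertoire` (class `pc_repertoire`), `report` (named
#'   integer vector of rejection counts by reason, plus `duplicate`), and
#'   `rejected` (data.frame of rejected rows and reasons).
#' @export
qc_filter <- function(records, thresholds = qc_thresholds(),
                      name = "repertoire") {
  if (is.character(records)) {
    records <- data.frame(sequence = toupper(records),
                          allotype = NA_character_, ion_score = NA_real_,
                          delta_mass_ppm = NA_real_, source_tpm = NA_real_,
                          row = seq_along(records), stringsAsFactors = FALSE)
  }
  stopifnot(inherits(thresholds, "pc_qc_thresholds"))
  th <- thresholds
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  len <- nchar(records$sequence)
  bad <- len < th$length_range[1] | len > th$length_range[2]
  reason[is.na(reason) & bad] <- "length"

  v <- records$ion_score
  bad <- if (th$require_ion_score) is.na(v) | v < th$min_ion_score else
    !is.na(v) & v < th$min_ion_score
  reason[is.na(reason) & bad] <- "ion_score"

  v <- records$delta_mass_ppm
  bad <- if (th$require_delta_mass) is.na(v) | abs(v) > th$max_delta_mass_ppm else
    !is.na(v) & abs(v) > th$max_delta_mass_ppm
  reason[is.na(reason) & bad] <- "delta_mass"

  v <- records$source_tpm
  bad <- if (th$require_tpm) is.na(v) | v < th$min_tpm else
    !is.na(v) & v < th$min_tpm
  reason[is.na(reason) & bad] <- "tpm"

  pass <- is.na(reason)
  # duplicates among passing records only (first passing occurrence kept);
  # failing rows are masked with unique sentinels so they never anchor a dup
  dup <- pass & duplicated(replace(records$sequence, which(!pass),
                                   paste0("\r", which(!pass))))
  keep <- pass & !dup

  rep_obj <- repertoire(records$sequence[keep], name = name,
                        length_range = th$length_range)
  reasons_all <- c("length", "ion_score", "delta_mass", "tpm")
  report <- vapply(reasons_all, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  report <- c(report, duplicate = sum(dup), retained = sum(keep))
  rejected <- data.frame(
    row = records$row[!keep],
    sequence = records$sequence[!keep],
    reason = ifelse(is.na(reason[!keep]), "duplicate", reason[!keep]),
    stringsAsFactors = FALSE
  )
  list(repertoire = rep_obj, report = report, rejected = rejected)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file
#'
#' Minimal FASTA reader returning a named character vector of sequences.
#' Header names are the first whitespace-delimited token after '>'.
#'
#' @param path FASTA file path.
#' @return Named character vector (uppercased sequences).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty FASTA: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (no leading '>'): ", path, call. = FALSE)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "\\s+"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, character(1),
                 collapse = "")
  out <- rep("", sum(hdr))
  out[as.integer(names(seqs))] <- seqs
  names(out) <- names_
  toupper(out)
}

#' Write a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Amino-acid composition of a protein FASTA
#'
#' Pools residue counts over all sequences and returns proportions over the
#' 20 canonical residues. Non-canonical letters (B, J, O, U, X, Z) are
#' excluded from both numerator and denominator.
#'
#' @param path FASTA file of protein sequences.
#' @return A `pc_background` composition (sums to 1).
#' @export
composition_from_fasta <- function(path) {
  seqs <- read_fasta(path)
  chars <- unlist(strsplit(paste0(seqs, collapse = ""), ""), use.names = FALSE)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  total <- sum(counts)
  if (total == 0) stop("no canonical residues in FASTA: ", path, call. = FALSE)
  freq <- as.numeric(counts) / total
  names(freq) <- AA_ALPHABET
  validate_background(freq)
}

# ---- HLA allele sequences ---------------------------------------------------

#' Read HLA allele protein sequences
#'
#' Reads allele protein sequences from FASTA and converts them to
#' mature-protein numbering by removing the signal peptide. HLA-A class I
#' heavy chains carry a 24-residue signal peptide, the default offset;
#' pass 0 for sequences that are already mature.
#'
#' @param path FASTA with allele names in headers.
#' @param signal_peptide_length Number of leading residues to strip
#'   (default 24).
#' @return List of `pc_allotype` records: `name`, `mature_sequence`.
#' @export
read_allele_sequences <- function(path, signal_peptide_length = 24L) {
  stopifnot(signal_peptide_length >= 0)
  seqs <- read_fasta(path)
  lapply(seq_along(seqs), function(i) {
    allotype_record(names(seqs)[i], seqs[[i]],
                    signal_peptide_length = signal_peptide_length)
  })
}

#' Construct an allotype record
#'
#' @param name Allele name.
#' @param sequence Protein sequence (precursor or mature).
#' @param signal_peptide_length Leading residues to strip (0 = already
#'   mature).
#' @return Object of class `pc_allotype`.
#' @export
allotype_record <- function(name, sequence, signal_peptide_length = 0L) {
  sequence <- toupper(sequence)
  mature <- substring(sequence, signal_peptide_length + 1L)
  if (nchar(mature) < 183L) {
    stop("allele ", name, ": mature sequence shorter than 183 residues (",
         nchar(mature), "); check the signal-peptide offset", call. = FALSE)
  }
  structure(list(name = name, mature_sequence = mature),
            class = "pc_allotype")
}

#' Binding-cleft residues at mature positions
#'
#' Returns the residue letter at each requested 1-based mature-protein
#' position (e.g. 62, 65, 66, 163 on the alpha-1/alpha-2 helices).
#'
#' @param record A `pc_allotype`.
#' @param positions Integer vector of mature positions.
#' @return Named character vector, names = positions.
#' @export
cleft_residues <- function(record, positions) {
  stopifnot(inherits(record, "pc_allotype"))
  positions <- as.integer(positions)
  n <- nchar(record$mature_sequence)
  if (any(positions < 1L | positions > n)) {
    stop("position out of range for ", record$name, " (mature length ", n,
         ")", call. = FALSE)
  }
  stats::setNames(substring(record$mature_sequence, positions, positions),
                  positions)
}

#' Write a repertoire and its QC report
#'
#' @param qc Result of [qc_filter()].
#' @param tsv_path Output TSV (sequence, allotype, pass, reason).
#' @param json_path Output JSON rejection report.
#' @export
write_qc_report <- function(qc, tsv_path, json_path) {
  kept <- data.frame(sequence = qc$repertoire$peptides,
                     pass = rep(TRUE, length(qc$repertoire$peptides)),
                     reason = rep("", length(qc$repertoire$peptides)),
                     stringsAsFactors = FALSE)
  rej <- data.frame(sequence = qc$rejected$sequence,
                    pass = rep(FALSE, nrow(qc$rejected)),
                    reason = qc$rejected$reason, stringsAsFactors = FALSE)
  out <- rbind(kept, rej)
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.list(qc$report), json_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(tsv_path)
}
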