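# PDB reading/writing and atom selections for HLA-peptide complex
# conformations and multi-model ensembles. (No pre-installed R package in
# this stack parses PDB, so the fixed-column format is handled here.)

#' Construct a conformation from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resnum` (integer),
#'   `icode` (character, "" if none), `resname`, `atom`, `element`, `x`,
#'   `y`, `z`.
#' @return Object of class `pc_conformation` (the validated data.frame,
#'   with a `topology` attribute).
#' @export
conformation <- function(atoms) {
  need <- c("chain", "resnum", "icode", "resname", "atom", "element",
            "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atom table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  atoms <- as.data.frame(atoms)[need]
  atoms$resnum <- as.integer(atoms$resnum)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  id <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom)
  if (anyDuplicated(id)) {
    stop("duplicate (chain, residue, atom) triples after altloc resolution",
         call. = FALSE)
  }
  rownames(atoms) <- NULL
  attr(atoms, "topology") <- paste(id, atoms$resname, collapse = ";")
  class(atoms) <- c("pc_conformation", "data.frame")
  atoms
}

topology_of <- function(conf) attr(conf, "topology")

#' Construct an ensemble of conformations
#'
#' @param conformations List of `pc_conformation` objects sharing one
#'   topology (same chains, residues and atom ordering).
#' @return Object of class `pc_ensemble`.
#' @export
ensemble <- function(conformations) {
  stopifnot(length(conformations) >= 1)
  topo <- topology_of(conformations[[1]])
  for (i in seq_along(conformations)) {
    if (!identical(topology_of(conformations[[i]]), topo)) {
      stop("conformation ", i, " differs in topology from frame 1",
           call. = FALSE)
    }
  }
  structure(list(conformations = conformations, topology = topo),
            class = "pc_ensemble")
}

#' @export
length.pc_ensemble <- function(x) length(x$conformations)

#' @export
print.pc_ensemble <- function(x, ...) {
  cat("<pc_ensemble> ", length(x$conformations), " frame(s), ",
      nrow(x$conformations[[1]]), " atoms\n", sep = "")
  invisible(x)
}

parse_pdb_atoms <- function(lines, keep_het = FALSE) {
  rec <- substr(lines, 1, 6)
  sel <- rec == "ATOM  " | (keep_het & rec == "HETATM")
  lines <- lines[sel]
  if (length(lines) == 0) return(NULL)
  df <- data.frame(
    atom = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resnum = as.integer(substr(lines, 23, 26)),
    icode = trimws(substr(lines, 27, 27)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  df$occupancy[is.na(df$occupancy)] <- 1
  df <- df[!df$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(df) == 0) return(NULL)
  # element fallback from the atom name when columns 77-78 are blank
  blank <- !nzchar(df$element)
  df$element[blank] <- substr(gsub("[0-9]", "", df$atom[blank]), 1, 1)
  # altloc: highest occupancy kept, ties broken by altloc label order
  if (any(nzchar(trimws(df$altloc)))) {
    key <- paste(df$chain, df$resnum, df$icode, df$atom)
    ord <- order(key, -df$occupancy, df$altloc)
    keep <- ord[!duplicated(key[ord])]
    df <- df[sort(keep), , drop = FALSE]
  }
  df
}

#' Read a PDB file into an ensemble
#'
#' Multi-model files map models to frames. Alternate locations are resolved
#' by highest occupancy (ties by altloc label order); waters and, by
#' default, heteroatoms are excluded.
#'
#' @param path PDB file.
#' @param keep_het Keep HETATM records (waters always dropped).
#' @return A `pc_ensemble`.
#' @export
read_structure <- function(path, keep_het = FALSE) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  frames <- if (length(model_starts) == 0) {
    list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    }
    Map(function(s, e) lines[(s + 1):(e - 1)], model_starts, ends)
  }
  confs <- lapply(frames, function(fl) {
    df <- parse_pdb_atoms(fl, keep_het = keep_het)
    if (is.null(df)) stop("no atoms parsed from ", path, call. = FALSE)
    conformation(df[c("chain", "resnum", "icode", "resname", "atom",
                      "element", "x", "y", "z")])
  })
  ensemble(confs)
}

#' Write a conformation or ensemble as PDB
#'
#' @param x A `pc_conformation` or `pc_ensemble`.
#' @param path Output path.
#' @export
write_structure <- function(x, path) {
  fmt_atom <- function(df) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(df)),
            ifelse(nchar(df$atom) < 4, paste0(" ", df$atom), df$atom),
            df$resname, df$chain, df$resnum,
            ifelse(nzchar(df$icode), df$icode, " "),
            df$x, df$y, df$z, 1, 0, df$element)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "pc_conformation")) {
    writeLines(fmt_atom(x), con)
    writeLines("END", con)
  } else if (inherits(x, "pc_ensemble")) {
    for (i in seq_along(x$conformations)) {
      writeLines(sprintf("MODEL %8d", i), con)
      writeLines(fmt_atom(x$conformations[[i]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    stop("x must be a pc_conformation or pc_ensemble", call. = FALSE)
  }
  invisible(path)
}

#' Select atoms by residue specification
#'
#' Residue selection syntax: a chain id (`"A"`) selects the whole chain;
#' `"A:65"` a residue; `"A:65B"` a residue with insertion code B. A
#' selection is a character vector of such specs; atom names may be
#' restricted with `atoms`.
#'
#' @param conf A `pc_conformation`.
#' @param sel Character vector of residue specs.
#' @param atoms Optional character vector of atom names to keep.
#' @return Integer row indices into `conf`.
#' @export
select_atoms <- function(conf, sel, atoms = NULL) {
  hit <- rep(FALSE, nrow(conf))
  for (s in sel) {
    if (grepl(":", s, fixed = TRUE)) {
      parts <- strsplit(s, ":", fixed = TRUE)[[1]]
      chain <- parts[1]
      m <- regmatches(parts[2], regexec("^(-?[0-9]+)([A-Za-z]?)$", parts[2]))[[1]]
      if (length(m) == 0) stop("bad residue spec: ", s, call. = FALSE)
      resnum <- as.integer(m[2])
      icode <- m[3]
      hit <- hit | (conf$chain == chain & conf$resnum == resnum &
                      conf$icode == icode)
    } else {
      hit <- hit | conf$chain == s
    }
  }
  idx <- which(hit)
  if (!is.null(atoms)) idx <- idx[conf$atom[idx] %in% atoms]
  if (length(idx) == 0) {
    stop("selection resolves to zero atoms: ", paste(sel, collapse = ","),
         call. = FALSE)
  }
  idx
}

# Residue identifier strings "chain:resnum[icode]" for atom rows.
residue_ids <- function(conf, idx = seq_len(nrow(conf))) {
  paste0(conf$chain[idx], ":", conf$resnum[idx], conf$icode[idx])
}
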