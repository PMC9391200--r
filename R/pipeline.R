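# Orchestration: QC -> frequencies -> logos -> co-occurrence -> grouping ->
# contacts, behind a validated config with deterministic file naming and a
# manifest. All outputs are pure functions of (inputs, config, seed).

PC_CONFIG_KEYS <- c("peptides", "simulate", "reference", "background",
                    "alleles", "signal_peptide_length", "structures",
                    "contact_selections", "classes", "thresholds", "out",
                    "seed", "log_level")

pc_log <- function(level, config, ...) {
  levels_ <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  want <- config$log_level %||% "info"
  if (levels_[[level %||% "info"]] >= levels_[[want]]) {
    message("[", level, "] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-insensitive 32-bit FNV-1a hash of the canonicalized config
config_hash <- function(config) {
  config$log_level <- NULL  # logging never alters results
  config$out <- NULL        # nor does the output location
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Validate a run configuration
#'
#' @param config Named list (e.g. from a JSON config file). Unknown keys
#'   are rejected.
#' @return The validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), PC_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$out)) stop("config needs 'out' directory",
                                call. = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  config$signal_peptide_length <-
    as.integer(config$signal_peptide_length %||% 24L)
  config$log_level <- config$log_level %||% "info"
  if (is.null(config$classes)) {
    config$classes <- list(list(name = "DE4", label = "p4",
                                members = c("D", "E")),
                           list(name = "KR1", label = "p1",
                                members = c("K", "R")))
  }
  config
}

#' Read a JSON run configuration
#' @param path JSON file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE))
}

load_background <- function(config) {
  if (is.null(config$background)) default_background() else
    composition_from_fasta(config$background)
}

load_repertoires <- function(config) {
  reps <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    for (nm in names(sim)) {
      s <- sim[[nm]]
      spec <- repertoire_spec(
        n = s$n %||% 5000L,
        p4_DE_freq = s$p4_DE_freq %||% 0.25,
        p1_KR_freq = s$p1_KR_freq %||% 0.25,
        coupling_or = s$coupling_or %||% 1.0,
        seed = derive_seed(config$seed, match(nm, names(sim)))
      )
      reps[[nm]] <- generate_repertoire(spec, name = nm)$repertoire
    }
  }
  th <- if (is.null(config$thresholds)) qc_thresholds() else
    do.call(qc_thresholds, config$thresholds)
  for (nm in names(config$peptides)) {
    recs <- read_peptide_table(config$peptides[[nm]])
    reps[[nm]] <- qc_filter(recs, th, name = nm)$repertoire
  }
  if (length(reps) == 0) stop("no repertoires configured", call. = FALSE)
  reps
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the QC stage
#' @param config Validated config.
#' @return Character vector of artifact paths.
#' @export
run_qc <- function(config) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  th <- if (is.null(config$thresholds)) qc_thresholds() else
    do.call(qc_thresholds, config$thresholds)
  stage("repertoire_io", {
    for (nm in names(config$peptides)) {
      recs <- read_peptide_table(config$peptides[[nm]])
      qc <- qc_filter(recs, th, name = nm)
      tsv <- file.path(config$out, paste0("qc_", nm, ".tsv"))
      js <- file.path(config$out, paste0("qc_", nm, ".json"))
      write_qc_report(qc, tsv, js)
      out <- c(out, tsv, js)
    }
  })
  out
}

#' Run the frequency/delta/test stage
#'
#' Emits per-repertoire frequency matrices and class frequencies, and --
#' when a reference repertoire is named -- delta matrices and per-cell
#' two-proportion Z tests against it.
#'
#' @param config Validated config (see [validate_config()]).
#' @param reps Optional pre-loaded named repertoire list.
#' @return Character vector of artifact paths.
#' @export
run_stats <- function(config, reps = NULL) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reps)) reps <- stage("repertoire_io", load_repertoires(config))
  out <- character(0)
  stage("positional_stats", {
    fms <- lapply(reps, frequency_matrix)
    for (nm in names(reps)) {
      f <- file.path(config$out, paste0("freq_", nm, ".tsv"))
      write_matrix_tsv(fms[[nm]], f)
      out <- c(out, f)
    }
    # class frequencies
    rows <- list()
    for (nm in names(reps)) {
      for (cl in config$classes) {
        cf <- class_frequency(reps[[nm]], cl$label,
                              residue_class(cl$name, cl$members))
        rows[[length(rows) + 1L]] <- data.frame(
          repertoire = nm, class = cl$name, label = cl$label,
          x = cf$x, n = cf$n, proportion = fmt_num(cf$proportion),
          stringsAsFactors = FALSE)
      }
    }
    f <- file.path(config$out, "class_frequencies.tsv")
    utils::write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, f)
    ref <- config$reference
    if (!is.null(ref)) {
      if (!ref %in% names(reps)) {
        stop("reference repertoire '", ref, "' not found", call. = FALSE)
      }
      for (nm in setdiff(names(reps), ref)) {
        delta <- frequency_difference(fms[[nm]], fms[[ref]])
        zt <- frequency_difference_tests(fms[[nm]], fms[[ref]])
        fd <- file.path(config$out, paste0("delta_", nm, "_vs_", ref,
                                           ".tsv"))
        fz <- file.path(config$out, paste0("ztest_", nm, "_vs_", ref,
                                           ".tsv"))
        write_matrix_tsv(delta, fd)
        write_matrix_tsv(zt$p, fz)
        out <- c(out, fd, fz)
      }
    }
  })
  out
}

#' Run the logo stage
#' @param config Validated config.
#' @param reps Optional pre-loaded repertoires.
#' @return Artifact paths.
#' @export
run_logo <- function(config, reps = NULL) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reps)) reps <- stage("repertoire_io", load_repertoires(config))
  bg <- stage("repertoire_io", load_background(config))
  out <- character(0)
  stage("motif_logo", {
    for (nm in names(reps)) {
      logo <- kl_logo(frequency_matrix(reps[[nm]]), bg)
      f <- file.path(config$out, paste0("logo_", nm, ".tsv"))
      write_logo_tsv(logo, f)
      out <- c(out, f)
    }
  })
  out
}

#' Run the co-occurrence stage (K/R1 x D/E4 per repertoire)
#' @param config Validated config.
#' @param reps Optional pre-loaded repertoires.
#' @return Artifact paths.
#' @export
run_cooccur <- function(config, reps = NULL) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reps)) reps <- stage("repertoire_io", load_repertoires(config))
  out <- character(0)
  stage("cooccurrence", {
    for (nm in names(reps)) {
      t <- contingency(reps[[nm]], "p1", class_KR(), "p4", class_DE())
      a <- association(t)
      f <- file.path(config$out, paste0("cooccur_", nm, ".tsv"))
      write_association_tsv(t, a, f)
      out <- c(out, f)
    }
  })
  out
}

#' Run the allotype-grouping stage
#' @param config Validated config; needs `alleles` (FASTA) unless
#'   `records` supplied.
#' @param reps Optional pre-loaded repertoires.
#' @param records Optional pre-loaded allotype records.
#' @return Artifact paths.
#' @export
run_group <- function(config, reps = NULL, records = NULL) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reps)) reps <- stage("repertoire_io", load_repertoires(config))
  if (is.null(records)) {
    if (is.null(config$alleles)) stop("grouping needs 'alleles' FASTA",
                                      call. = FALSE)
    recs <- stage("repertoire_io", read_allele_sequences(
      config$alleles, config$signal_peptide_length))
    records <- stats::setNames(recs, vapply(recs, `[[`, character(1),
                                            "name"))
  }
  out <- character(0)
  stage("allotype_catalog", {
    g <- group_class_frequencies(reps, records)
    f <- file.path(config$out, "group_frequencies.tsv")
    tab <- g$table
    tab$frequency <- fmt_num(tab$frequency)
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, f)
    if (!is.null(g$tests)) {
      ft <- file.path(config$out, "group_tests.tsv")
      pw <- g$tests$pairwise
      for (cn in c("t", "df", "p_welch", "p_adjusted")) {
        pw[[cn]] <- fmt_num(pw[[cn]])
      }
      utils::write.table(pw, ft, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fo <- file.path(config$out, "group_omnibus.tsv")
      write_tests_tsv(list(omnibus = g$tests$omnibus), fo)
      out <- c(out, ft, fo)
    }
  })
  out
}

#' Run the structure-contacts stage
#' @param config Validated config; needs `structures` (named PDB paths).
#' @return Artifact paths.
#' @export
run_contacts <- function(config) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  crit <- contact_criteria()
  selA <- config$contact_selections$selA %||% "A"
  selB <- config$contact_selections$selB %||% "P"
  stage("structure_contacts", {
    for (nm in names(config$structures)) {
      ens <- read_structure(config$structures[[nm]])
      prev <- contact_prevalence(ens, crit, selA, selB)
      prev$prevalence <- fmt_num(prev$prevalence)
      f <- file.path(config$out, paste0("contacts_", nm, ".tsv"))
      utils::write.table(prev, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      prov <- file.path(config$out, paste0("contacts_", nm,
                                           "_provenance.json"))
      jsonlite::write_json(list(criteria = unclass(crit),
                                selA = selA, selB = selB),
                           prov, auto_unbox = TRUE, pretty = TRUE)
      out <- c(out, f, prov)
    }
  })
  out
}

#' Run the simulate stage (write generated fixtures)
#' @param config Validated config with a `simulate` block.
#' @return Artifact paths.
#' @export
run_simulate <- function(config) {
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  stage("synthetic_data", {
    sim <- config$simulate
    if (is.null(sim)) stop("no 'simulate' block in config", call. = FALSE)
    for (nm in names(sim)) {
      s <- sim[[nm]]
      spec <- repertoire_spec(
        n = s$n %||% 5000L,
        p4_DE_freq = s$p4_DE_freq %||% 0.25,
        p1_KR_freq = s$p1_KR_freq %||% 0.25,
        coupling_or = s$coupling_or %||% 1.0,
        seed = derive_seed(config$seed, match(nm, names(sim))))
      gen <- generate_repertoire(spec, name = nm)
      tsv <- file.path(config$out, paste0("sim_", nm, ".tsv"))
      js <- file.path(config$out, paste0("sim_", nm, "_truth.json"))
      write_repertoire_fixture(gen, tsv, js)
      out <- c(out, tsv, js)
    }
  })
  out
}

#' Run the full pipeline
#'
#' Executes every configured stage and writes a manifest listing each
#' artifact with the config hash, package version and seed.
#'
#' @param config Config list or path to a JSON config.
#' @return Invisibly, the manifest path.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  pc_log("info", config, "starting full run (seed ", config$seed, ")")
  artifacts <- character(0)
  reps <- stage("repertoire_io", load_repertoires(config))
  pc_log("info", config, length(reps), " repertoire(s): ",
         paste(names(reps), vapply(reps, length, integer(1)),
               sep = "=", collapse = " "))
  if (!is.null(config$peptides) && length(config$peptides) > 0) {
    artifacts <- c(artifacts, run_qc(config))
  }
  if (!is.null(config$simulate)) artifacts <- c(artifacts,
                                                run_simulate(config))
  artifacts <- c(artifacts, run_stats(config, reps))
  artifacts <- c(artifacts, run_logo(config, reps))
  artifacts <- c(artifacts, run_cooccur(config, reps))
  if (!is.null(config$alleles)) {
    artifacts <- c(artifacts, run_group(config, reps))
  }
  if (!is.null(config$structures)) {
    artifacts <- c(artifacts, run_contacts(config))
  }
  manifest <- file.path(config$out, "manifest.json")
  jsonlite::write_json(list(
    config_hash = config_hash(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("pepcleft")),
    artifacts = basename(artifacts)
  ), manifest, auto_unbox = TRUE, pretty = TRUE)
  pc_log("info", config, "wrote ", length(artifacts), " artifact(s)")
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `qc`, `stats`, `logo`, `cooccur`, `group`, `contacts`,
#' `simulate`, `full`. The first argument is the subcommand; `--config
#' file.json` supplies the structured config, and the flags `--peptides`
#' (name=path, comma-separated), `--background`, `--alleles`,
#' `--structures` (name=path), `--reference`, `--out`, `--seed`,
#' `--log-level` override config keys.
#'
#' @param args Character vector (default: command-line arguments).
#' @return Invisibly, the artifact paths (or manifest path for `full`).
#' @export
pepcleft_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop("usage: pepcleft <qc|stats|logo|cooccur|group|contacts|simulate|",
         "full> [--config f.json] [--out dir] ...", call. = FALSE)
  }
  cmd <- args[[1]]
  args <- args[-1]
  config <- list()
  i <- 1L
  parse_named <- function(v) {
    parts <- strsplit(strsplit(v, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(lapply(parts, `[`, 2), vapply(parts, `[`, character(1),
                                                  1))
  }
  while (i <= length(args)) {
    key <- args[[i]]
    val <- if (i + 1L <= length(args)) args[[i + 1L]] else
      stop("missing value for ", key, call. = FALSE)
    switch(key,
           "--config" = { config <- utils::modifyList(
             jsonlite::read_json(val, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE), config) },
           "--peptides" = { config$peptides <- parse_named(val) },
           "--structures" = { config$structures <- parse_named(val) },
           "--background" = { config$background <- val },
           "--alleles" = { config$alleles <- val },
           "--reference" = { config$reference <- val },
           "--out" = { config$out <- val },
           "--seed" = { config$seed <- as.integer(val) },
           "--log-level" = { config$log_level <- val },
           stop("unknown flag: ", key, call. = FALSE))
    i <- i + 2L
  }
  config <- validate_config(config)
  fn <- switch(cmd,
               qc = run_qc, stats = run_stats, logo = run_logo,
               cooccur = run_cooccur, group = run_group,
               contacts = run_contacts, simulate = run_simulate,
               full = run_full,
               stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(fn(config))
}
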