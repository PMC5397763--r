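# End-to-end orchestration: simulate -> coevolve -> psn -> interface ->
# metrics -> summary, driven by a plain-text config with strict unknown-key
# rejection. All outputs are TSV with header comments recording the stage and
# the config hash; a fixed config + seed reproduces byte-identical files.

# schema: section -> key -> list(default, type)
# types: int, num, str, pairs ("3:4,6:7"), ints ("2,5,8")
config_schema <- function() {
  list(
    run = list(
      seed = list(1L, "int"),
      outdir = list("interlock_out", "str")
    ),
    inputs = list(
      msa_a = list("", "str"),
      msa_b = list("", "str"),
      ensemble = list("", "str")
    ),
    simulate = list(
      n_seqs = list(100L, "int"),
      length_a = list(60L, "int"),
      length_b = list(60L, "int"),
      coupling_i = list(10L, "int"),
      coupling_j = list(80L, "int"),
      coupling_strength = list(0.9, "num"),
      gap_fraction = list(0.05, "num"),
      n_res_a = list(12L, "int"),
      n_res_b = list(12L, "int"),
      contact_pairs = list("3:4,6:7", "pairs"),
      hbond_pairs = list("3:4", "pairs"),
      path_chain = list("2,5,8,11", "ints"),
      n_frames = list(10L, "int"),
      noise_sd = list(0.05, "num"),
      broken_fraction = list(0.2, "num")
    ),
    coevolve = list(
      a = list(0.05, "num"),
      b = list(10, "num"),
      top_n = list(24L, "int"),
      min_separation = list(5L, "int"),
      max_gap_fraction = list(0.30, "num")
    ),
    psn = list(
      i_min = list("auto", "str"),
      contact_cutoff = list(4.5, "num"),
      exclude_neighbors = list(2L, "int"),
      stability = list(0.5, "num"),
      source = list("", "str"),
      sink = list("", "str")
    ),
    interface = list(
      chain_a = list("A", "str"),
      chain_b = list("B", "str"),
      interface_cutoff = list(5.0, "num"),
      da_cutoff = list(3.5, "num"),
      stride = list(1L, "int"),
      e_hbond = list(-1.5, "num"),
      e_elec = list(1.0, "num"),
      elec_cutoff = list(6.0, "num"),
      e_vdw = list(-0.2, "num"),
      vdw_lo = list(3.0, "num"),
      vdw_hi = list(5.0, "num"),
      hotspot_threshold = list(-2.0, "num")
    ),
    metrics = list(
      rmsf_window = list(0.5, "num")
    )
  )
}

parse_config_value <- function(raw, type) {
  switch(type,
    int = as.integer(raw),
    num = as.numeric(raw),
    str = raw,
    pairs = {
      if (!nzchar(trimws(raw))) list()
      else lapply(strsplit(trimws(raw), "\\s*,\\s*")[[1]], function(p) {
        as.integer(strsplit(p, ":")[[1]])
      })
    },
    ints = {
      if (!nzchar(trimws(raw))) integer()
      else as.integer(strsplit(trimws(raw), "\\s*,\\s*")[[1]])
    }
  )
}

#' Default pipeline configuration
#'
#' The documented defaults of every stage in one nested list. Thresholds
#' default to the conventional values used throughout the package:
#' gap filter 0.30, I_min 2.5 (with `"auto"` calibration from the
#' largest-cluster transition), dynamic stability 0.5, frame stride 1.
#'
#' @return Nested named list (section -> key -> value) of class `run_config`.
#' @export
default_run_config <- function() {
  sch <- config_schema()
  cfg <- lapply(sch, function(sec) {
    lapply(sec, function(entry) {
      v <- entry[[1]]
      if (entry[[2]] %in% c("pairs", "ints")) parse_config_value(v, entry[[2]]) else v
    })
  })
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration file
#'
#' Plain-text `key = value` format with `[section]` headers and `#` comments.
#' Unknown sections or keys are rejected (strict mode): a silent typo would
#' quietly change threshold semantics.
#'
#' @param path Path to the config file.
#' @return A `run_config` list (all defaults filled in).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_interlock(sprintf("config file not found: %s", path),
                   "interlock_config_error")
  }
  sch <- config_schema()
  cfg <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  section <- NA_character_
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[[ln]])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    if (grepl("^\\[.+\\]$", raw)) {
      section <- gsub("^\\[|\\]$", "", raw)
      if (!section %in% names(sch)) {
        stop_interlock(sprintf("unknown config section [%s] (line %d)",
                               section, ln), "interlock_config_error")
      }
      next
    }
    kv <- regmatches(raw, regexec("^([^=]+)=(.*)$", raw))[[1]]
    if (length(kv) != 3 || is.na(section)) {
      stop_interlock(sprintf("malformed config line %d: %s", ln, raw),
                     "interlock_config_error")
    }
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (!key %in% names(sch[[section]])) {
      stop_interlock(sprintf("unknown key '%s' in section [%s] (line %d)",
                             key, section, ln), "interlock_config_error")
    }
    cfg[[section]][[key]] <- parse_config_value(val, sch[[section]][[key]][[2]])
  }
  cfg
}

# normalized config text (used for the recorded hash and config_used.ini)
config_text <- function(cfg) {
  sch <- config_schema()
  out <- character()
  for (sec in names(sch)) {
    out <- c(out, sprintf("[%s]", sec))
    for (key in names(sch[[sec]])) {
      v <- cfg[[sec]][[key]]
      txt <- if (is.list(v)) {
        paste(vapply(v, paste, character(1), collapse = ":"), collapse = ",")
      } else paste(v, collapse = ",")
      out <- c(out, sprintf("%s = %s", key, txt))
    }
    out <- c(out, "")
  }
  out
}

# TSV writer with stage/config-hash header comments; deterministic formatting
write_stage_tsv <- function(df, path, stage, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# interlock %s", stage),
               sprintf("# config %s", hash)), con)
  df <- as.data.frame(df)
  for (c in names(df)) {
    if (is.numeric(df[[c]]) && !is.integer(df[[c]])) {
      df[[c]] <- sprintf("%.6g", df[[c]])
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, coevolve, psn, interface and metrics stages from one
#' configuration, writing all result tables as TSV plus a one-file summary.
#' With the same config and seed the outputs are byte-identical across runs.
#' External inputs can replace the simulated ones via the `[inputs]` section
#' (aligned FASTA for the two domains, a multi-model PDB for the ensemble).
#'
#' @param config A `run_config` list ([default_run_config()],
#'   [read_run_config()]) or a path to a config file.
#' @param outdir Output directory (created if needed); overrides the config's
#'   `run.outdir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the result objects and output file paths.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (quiet) {
    oldopt <- options(interlock.quiet = TRUE)
    on.exit(options(oldopt))
  }
  log <- if (quiet) function(...) invisible() else pipeline_log
  outdir <- outdir %||% config$run$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$run$seed

  cfg_path <- file.path(outdir, "config_used.ini")
  writeLines(config_text(config), cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  paths <- list(config = cfg_path)
  out <- list()

  # ---- simulate / load inputs ----
  sim <- config$simulate
  if (nzchar(config$inputs$msa_a)) {
    for (f in c(config$inputs$msa_a, config$inputs$msa_b)) {
      if (!file.exists(f)) {
        stop_interlock(sprintf("coevolve stage: input file not found: %s", f),
                       "interlock_config_error")
      }
    }
    log("simulate", "skipped for alignments; using provided FASTA inputs")
    msa_a <- read_fasta_alignment(config$inputs$msa_a)
    msa_b <- read_fasta_alignment(config$inputs$msa_b)
    truth <- NULL
  } else {
    log("simulate", "alignment: %d sequences, %d + %d columns",
        sim$n_seqs, sim$length_a, sim$length_b)
    gen <- generate_coupled_msa(
      n_seqs = sim$n_seqs, length_a = sim$length_a, length_b = sim$length_b,
      couplings = list(coupling_spec(sim$coupling_i, sim$coupling_j,
                                     sim$coupling_strength)),
      gap_fraction = sim$gap_fraction, seed = seed
    )
    msa_a <- gen$msa_a; msa_b <- gen$msa_b; truth <- gen$truth
    paths$msa_a <- write_fasta_alignment(msa_a, file.path(outdir, "msa_a.fasta"))
    paths$msa_b <- write_fasta_alignment(msa_b, file.path(outdir, "msa_b.fasta"))
    write_stage_tsv(truth, file.path(outdir, "msa_truth.tsv"), "simulate", hash)
  }
  if (nzchar(config$inputs$ensemble)) {
    if (!file.exists(config$inputs$ensemble)) {
      stop_interlock(sprintf("psn stage: input file not found: %s",
                             config$inputs$ensemble), "interlock_config_error")
    }
    ens <- read_pdb(config$inputs$ensemble)
    spec <- NULL
  } else {
    log("simulate", "toy complex: %d + %d residues, %d frames",
        sim$n_res_a, sim$n_res_b, sim$n_frames)
    spec <- toy_complex_spec(
      n_res_a = sim$n_res_a, n_res_b = sim$n_res_b,
      contact_pairs = sim$contact_pairs, hbond_pairs = sim$hbond_pairs,
      path_chain = if (length(sim$path_chain)) sim$path_chain else NULL
    )
    base <- generate_toy_complex(spec, seed = seed)
    ens <- generate_ensemble(base, n_frames = sim$n_frames,
                             noise_sd = sim$noise_sd,
                             broken_fraction = sim$broken_fraction,
                             seed = seed)
    paths$ensemble <- write_pdb(ens, file.path(outdir, "ensemble.pdb"))
    write_toy_truth(spec, file.path(outdir, "complex_truth.tsv"))
  }

  # ---- coevolve ----
  cv <- config$coevolve
  log("coevolve", "scoring all column pairs")
  coev <- predict_coevolving_pairs(
    msa_a, msa_b,
    params = pseudocount_params(cv$a, cv$b),
    top_n = cv$top_n, max_gap_fraction = cv$max_gap_fraction,
    min_separation = cv$min_separation
  )
  paths$pairs <- write_stage_tsv(tidy(coev), file.path(outdir, "pairs.tsv"),
                                 "coevolve", hash)
  out$coevolution <- coev

  # ---- psn ----
  ps <- config$psn
  first <- get_snapshot(ens, 1)
  params0 <- network_params(contact_cutoff = ps$contact_cutoff, i_min = 0,
                            exclude_neighbors = ps$exclude_neighbors)
  if (identical(ps$i_min, "auto")) {
    prof <- largest_cluster_profile(first, params = params0)
    sel <- select_imin(prof)
    i_min <- if (sel$transition_found) sel$i_min else 2.5
    log("psn", "I_min %s from largest-cluster transition",
        format(i_min))
  } else {
    i_min <- as.numeric(ps$i_min)
  }
  params <- network_params(contact_cutoff = ps$contact_cutoff, i_min = i_min,
                           exclude_neighbors = ps$exclude_neighbors)
  src <- ps$source; snk <- ps$sink
  if (!nzchar(src) || !nzchar(snk)) {
    if (!is.null(spec) && !is.null(spec$path_chain)) {
      pc <- spec$path_chain
      src <- paste0(spec$path_chain_id, ":", pc[1])
      snk <- paste0(spec$path_chain_id, ":", pc[length(pc)])
    } else {
      stop_interlock("psn stage: source/sink residues must be configured",
                     "interlock_config_error")
    }
  }
  log("psn", "paths %s -> %s at I_min %.2f%%", src, snk, i_min)
  pr <- ensemble_paths(ens, src, snk, params, stability = ps$stability)
  paths$edges <- write_stage_tsv(tidy(pr$ensemble_network),
                                 file.path(outdir, "edges.tsv"), "psn", hash)
  paths$paths <- write_stage_tsv(tidy(pr), file.path(outdir, "paths.tsv"),
                                 "psn", hash)
  consensus <- tibble(node_id = pr$consensus_nodes)
  paths$consensus <- write_stage_tsv(consensus,
                                     file.path(outdir, "consensus.tsv"),
                                     "psn", hash)
  out$paths <- pr

  # ---- interface ----
  ifc <- config$interface
  ecfg <- energy_config(
    e_hbond = ifc$e_hbond, e_elec = ifc$e_elec, elec_cutoff = ifc$elec_cutoff,
    e_vdw = ifc$e_vdw, vdw_range = c(ifc$vdw_lo, ifc$vdw_hi),
    interface_cutoff = ifc$interface_cutoff,
    hotspot_threshold = ifc$hotspot_threshold,
    criteria = hbond_criteria(da_cutoff = ifc$da_cutoff)
  )
  log("interface", "H-bond occupancy, energies, hotspots (chains %s/%s)",
      ifc$chain_a, ifc$chain_b)
  iface <- interface_residues(first, ifc$chain_a, ifc$chain_b,
                              cutoff = ifc$interface_cutoff)
  occ <- hbond_occupancy(ens, ecfg$criteria)
  ets <- energy_time_series(ens, ecfg, ifc$chain_a, ifc$chain_b,
                            stride = ifc$stride)
  hs <- hotspots(first, ecfg, ifc$chain_a, ifc$chain_b)
  paths$interface <- write_stage_tsv(iface, file.path(outdir, "interface.tsv"),
                                     "interface", hash)
  paths$hbonds <- write_stage_tsv(occ, file.path(outdir, "hbonds.tsv"),
                                  "interface", hash)
  paths$energies <- write_stage_tsv(ets, file.path(outdir, "energies.tsv"),
                                    "interface", hash)
  paths$hotspots <- write_stage_tsv(hs, file.path(outdir, "hotspots.tsv"),
                                    "interface", hash)
  out$interface <- list(residues = iface, occupancy = occ, energies = ets,
                        hotspots = hs)

  # ---- metrics ----
  log("metrics", "RMSD, Rg, RMSF")
  met <- dplyr::left_join(rmsd_series(ens), rg_series(ens),
                          by = c("frame", "time"))
  rf <- rmsf(ens, window = config$metrics$rmsf_window)
  paths$metrics <- write_stage_tsv(met, file.path(outdir, "metrics.tsv"),
                                   "metrics", hash)
  paths$rmsf <- write_stage_tsv(rf, file.path(outdir, "rmsf.tsv"),
                                "metrics", hash)
  out$metrics <- list(series = met, rmsf = rf)

  # ---- summary ----
  g <- glance(coev)
  planted_rank <- NA_integer_
  if (!is.null(truth) && nrow(truth)) {
    hit <- coev$all_pairs$i == truth$i[1] & coev$all_pairs$j == truth$j[1]
    if (any(hit)) planted_rank <- coev$all_pairs$rank[hit][1]
  }
  summary_tbl <- tibble(
    key = c("pairs_reported", "pairs_inter", "pairs_intra_a", "pairs_intra_b",
            "planted_pair_rank", "stable_hbonds", "average_path_length",
            "consensus_path", "i_min", "n_interface_residues",
            "normalized_energy_per_residue", "mean_rmsd", "mean_rg"),
    value = c(g$n_pairs_reported, g$n_inter, g$n_intra_a, g$n_intra_b,
              planted_rank, sum(occ$stable),
              sprintf("%.4g", pr$average_length),
              paste(pr$consensus_nodes, collapse = ","),
              sprintf("%.4g", i_min), nrow(iface),
              sprintf("%.4g", mean(ets$normalized_per_residue, na.rm = TRUE)),
              sprintf("%.4g", mean(met$rmsd)), sprintf("%.4g", mean(met$rg)))
  )
  paths$summary <- write_stage_tsv(summary_tbl, file.path(outdir, "summary.tsv"),
                                   "summary", hash)
  out$summary <- summary_tbl
  out$paths_written <- paths
  log("run", "done: %d files in %s", length(paths), outdir)
  invisible(out)
}
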