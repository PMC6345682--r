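# Pipeline orchestration: a flat key=value run configuration drives the
# individual analyses (superposition, composition, surface, ligand transfer,
# phylogeny) and writes one TSV per stage plus a combined comparison table
# and a structured log. Reproducibility contract: identical config => byte
# identical outputs (all randomness is seeded from the config).

#' Read a flat key=value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Repeated keys
#' become vectors (used for multiple reference structures).
#'
#' @param path Config file path.
#' @return Named list of character values (class `run_config`).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3)
  if (length(bad)) {
    stop("malformed config line: '", lines[bad[1]], "'", call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  cfg <- lapply(split(vals, factor(keys, levels = unique(keys))), unname)
  class(cfg) <- "run_config"
  cfg
}

cfg_get <- function(config, key, default = NULL) {
  if (is.null(config[[key]])) default else config[[key]]
}

cfg_flag <- function(config, key) {
  tolower(cfg_get(config, key, "false")) %in% c("true", "1", "yes", "on")
}

#' Validate a run configuration
#'
#' Problems are returned as data, not raised: missing files, invalid chain
#' selectors, missing seeds for stochastic stages. An empty result means the
#' config is runnable.
#'
#' @param config A `run_config` (or named list).
#' @return Character vector of problem descriptions (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need_file <- function(key) {
    for (p in cfg_get(config, key, character(0))) {
      if (!file.exists(p)) {
        problems <<- c(problems, sprintf("%s: file does not exist: %s", key, p))
      }
    }
  }
  for (key in c("target_pdb", "ref_pdb", "query_fasta", "ref_fasta",
                "surface_pdb", "msa", "ligand_ref_pdb")) {
    need_file(key)
  }
  check_chain <- function(pdb_key, chain_key) {
    paths <- cfg_get(config, pdb_key)
    chains <- cfg_get(config, chain_key)
    if (is.null(paths) || is.null(chains)) return()
    p <- paths[1]
    if (!file.exists(p)) return()
    ids <- chain_ids(read_structure(p))
    for (ch in strsplit(chains[1], "")[[1]]) {
      if (!ch %in% ids) {
        problems <<- c(problems,
                       sprintf("%s: chain '%s' absent from %s", chain_key, ch, p))
      }
    }
  }
  check_chain("target_pdb", "target_chains")
  check_chain("ref_pdb", "ref_chains")
  for (stage_seed in c("surface_seed", "phylo_seed")) {
    stage <- sub("_seed$", "", stage_seed)
    if (cfg_flag(config, paste0("run_", stage)) &&
        is.null(config[[stage_seed]])) {
      problems <- c(problems, sprintf("%s requires an explicit %s", stage, stage_seed))
    }
  }
  problems
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparison pipeline
#'
#' Executes the toggled stages (`run_superpose`, `run_composition`,
#' `run_surface`, `run_ligand`, `run_phylo`) and writes one TSV per stage to
#' the output directory, a combined structure-comparison table (one row per
#' reference entry: monomer/dimer RMSD, aligned residue counts, identity),
#' and a log recording parameters and seeds. A stage failure raises an error
#' naming the stage; outputs of earlier stages are preserved.
#'
#' @param config A `run_config` or path to one.
#' @return Named list of written file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid config:\n", paste(" -", problems, collapse = "\n"), call. = FALSE)
  }
  out_dir <- cfg_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("halogst %s", as.character(utils::packageVersion("halogst"))),
                 sprintf("R %s", getRversion()))
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (cfg_flag(config, "run_superpose")) {
    outputs$superpose <- stage("superpose", {
      target <- read_structure(cfg_get(config, "target_pdb"))
      tch <- strsplit(cfg_get(config, "target_chains", "A"), "")[[1]]
      cycles <- as.integer(cfg_get(config, "cycles", "5"))
      reject <- as.numeric(cfg_get(config, "reject_factor", "2"))
      refs <- cfg_get(config, "ref_pdb")
      rchs <- strsplit(cfg_get(config, "ref_chains",
                               paste(rep("A", length(refs)), collapse = " ")),
                       "\\s+")[[1]]
      rows <- lapply(seq_along(refs), function(k) {
        ref <- read_structure(refs[k])
        rch <- strsplit(rchs[min(k, length(rchs))], "")[[1]]
        mono <- superpose_monomer(target, tch[1], ref, rch[1],
                                  cycles = cycles, reject_factor = reject)
        row <- data.frame(
          entry = ref$id, rmsd_monomer = round(mono$rmsd, 2),
          n_aligned_monomer = mono$n_aligned,
          rmsd_dimer = NA_real_, n_aligned_dimer = NA_integer_,
          identity_pct = round(mono$identity_percent, 2),
          stringsAsFactors = FALSE
        )
        if (length(tch) == 2 && length(rch) == 2) {
          dim_ <- superpose_dimer(target, tch, ref, rch,
                                  cycles = cycles, reject_factor = reject)
          row$rmsd_dimer <- round(dim_$rmsd, 2)
          row$n_aligned_dimer <- dim_$n_aligned
        }
        row
      })
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(out_dir, "comparison_table.tsv"))
    })
    log_lines <- c(log_lines, "stage superpose: ok")
  } else {
    log_lines <- c(log_lines, "stage superpose: skipped (toggle off)")
  }

  if (cfg_flag(config, "run_composition")) {
    outputs$composition <- stage("composition", {
      q <- read_fasta(cfg_get(config, "query_fasta"))
      r <- read_fasta(cfg_get(config, "ref_fasta"))
      d <- composition_delta(q[[1]], r[[1]],
                             query_id = names(q)[1], reference_id = names(r)[1])
      write_tsv(composition_report(d),
                file.path(out_dir, "composition_delta.tsv"))
    })
    log_lines <- c(log_lines, "stage composition: ok")
  } else {
    log_lines <- c(log_lines, "stage composition: skipped (toggle off)")
  }

  if (cfg_flag(config, "run_surface")) {
    outputs$surface <- stage("surface", {
      s <- read_structure(cfg_get(config, "surface_pdb"))
      seed <- as.integer(cfg_get(config, "surface_seed", "1"))
      n_perm <- as.integer(cfg_get(config, "n_perm", "999"))
      sasa <- shrake_rupley(s,
                            probe_radius = as.numeric(cfg_get(config, "probe", "1.4")))
      cs <- coulomb_surface(s, sasa)
      tab <- sasa$residue
      tab$surface_flag <- tab$rel_sasa >= as.numeric(cfg_get(config, "rel_threshold", "0.25"))
      tab$coulomb_score <- cs$coulomb_score[match(tab$residue_id, cs$residue_id)]
      ev <- tryCatch(
        charge_evenness(s, sasa, n_perm = n_perm, seed = seed),
        error = function(e) NULL
      )
      log_lines <<- c(log_lines,
                      if (is.null(ev)) "surface: evenness not computable"
                      else sprintf("surface: evenness stat %.3f p %.4f (seed %d, n_perm %d)",
                                   ev$statistic, ev$p_clustered, seed, n_perm))
      write_tsv(tab, file.path(out_dir, "surface.tsv"))
    })
    log_lines <- c(log_lines, "stage surface: ok")
  } else {
    log_lines <- c(log_lines, "stage surface: skipped (toggle off)")
  }

  if (cfg_flag(config, "run_ligand")) {
    outputs$ligand <- stage("ligand", {
      target <- read_structure(cfg_get(config, "target_pdb"))
      ref <- read_structure(cfg_get(config, "ligand_ref_pdb"))
      tch <- substr(cfg_get(config, "target_chains", "A"), 1, 1)
      rch <- substr(cfg_get(config, "ligand_ref_chain", "A"), 1, 1)
      sup <- superpose_monomer(ref, rch, target, tch)
      lig <- transplant_ligand(target, ref, cfg_get(config, "ligand_resname", "GSH"), sup)
      if (cfg_flag(config, "truncate_to_gec")) lig <- truncate_gsh_to_gec(lig)
      clashes <- detect_clashes(lig, target,
                                tolerance = as.numeric(cfg_get(config, "clash_tolerance", "0.4")))
      write_tsv(clashes, file.path(out_dir, "ligand_clashes.tsv"))
    })
    log_lines <- c(log_lines, "stage ligand: ok")
  } else {
    log_lines <- c(log_lines, "stage ligand: skipped (toggle off)")
  }

  if (cfg_flag(config, "run_phylo")) {
    outputs$phylo <- stage("phylo", {
      msa <- read_alignment(cfg_get(config, "msa"))
      st <- bootstrap_support(
        msa,
        n_reps = as.integer(cfg_get(config, "boot", "100")),
        seed = as.integer(cfg_get(config, "phylo_seed", "1")),
        threshold = as.numeric(cfg_get(config, "boot_threshold", "40"))
      )
      nwk <- file.path(out_dir, "tree.nwk")
      writeLines(write_newick(st), nwk)
      nwk
    })
    log_lines <- c(log_lines, "stage phylo: ok")
  } else {
    log_lines <- c(log_lines, "stage phylo: skipped (toggle off)")
  }

  log_path <- file.path(out_dir, "run.log")
  writeLines(log_lines, log_path)
  outputs$log <- log_path
  invisible(outputs)
}
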