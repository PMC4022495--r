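# Orchestration of the full apo-vs-holo comparative analysis: load (or
# synthesize) open and closed swapped-dimer structures, then run
# superposition/RMSD, closure analysis, buried interface areas, interaction
# censuses with C/O-interface classification, ligand-pocket inventory,
# sequence metrics, stereochemistry statistics and (optionally) the ITC fit,
# collecting per-stage errors instead of aborting.

#' Default analysis configuration
#'
#' Residue ranges default to the TmArgBP layout (lobe I 23-110 + 210-231,
#' lobe II 116-203, hinge 232-236, swapped helix 237-246, main body 20-233);
#' when structures are synthesized, ranges from the generator are used
#' instead.  Unknown keys in overrides are rejected.
#'
#' @param ... overrides of the default keys.
#' @return config list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    apo = list(fixture = list(n_res_per_lobe = 30, linker_length = 5,
                              helix_tail_length = 10, seed = 1)),
    holo = NULL,            # NULL with fixture apo: closed conformer derived
    closure_angle = 84,     # degrees, used to derive the closed conformer
    chain_map = NULL,
    domains = list(lobe1 = "23-110,210-231", lobe2 = "116-203",
                   hinge = c(232, 236), swapped = c(237, 246),
                   main_body = c(20, 233)),
    cutoffs = list(salt_bridge = 4.0, hbond_dmax = 3.5, hbond_angle = 120,
                   hydrophobic = 4.5),
    sasa = list(probe = 1.4, n_points = 960),
    psi_windows = list(c(75, 105), c(135, 165)),
    sequence = NULL,        # list(one_letter, first_number) or NULL
    measured_masses_kda = NULL,
    ligand = list(resid = "ARG"),
    itc = NULL,             # list(design = itc_design(), heats = <numeric>)
    seed = 1)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  class(cfg) <- "analysis_config"
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  if (res$ok) report$results[[name]] <- res$value
  else report$errors[[name]] <- res$error
  report
}

load_or_build <- function(side_cfg, closure_angle = NULL) {
  if (is.null(side_cfg)) return(NULL)
  if (!is.null(side_cfg$path)) {
    return(list(structure = read_pdb(side_cfg$path), generated = FALSE,
                domains = NULL, annotation = NULL))
  }
  if (!is.null(side_cfg$fixture)) {
    mono <- make_two_lobe_monomer(side_cfg$fixture)
    if (!is.null(closure_angle)) {
      ca1 <- colMeans(select_atoms(mono$structure, mono$domains$lobe1,
                                   "CA")$xyz)
      ca2 <- colMeans(select_atoms(mono$structure, mono$domains$lobe2,
                                   "CA")$xyz)
      u <- unitv(ca2 - ca1)
      cands <- list(cross3(u, c(0, 0, 1)), cross3(u, c(0, 1, 0)),
                    cross3(u, c(1, 0, 0)))
      cands <- Filter(function(v) vnorm(v) > 1e-6, cands)
      cands <- c(cands, lapply(cands, function(v) -v))
      built <- NULL
      for (axis in cands) {
        closed <- apply_domain_rotation(mono$structure, mono$domains$lobe2,
                                        axis, closure_angle, pivot = ca2)
        built <- tryCatch({
          m2 <- mono; m2$structure <- closed
          list(mono = m2, dimer = make_swapped_dimer(m2))
        }, error = function(e) NULL)
        if (!is.null(built)) break
      }
      if (is.null(built))
        stop("no closure axis admitted a clash-free closed dimer")
      mono <- built$mono
      return(list(structure = built$dimer, monomer = mono$structure,
                  generated = TRUE, domains = mono$domains,
                  annotation = mono$annotation))
    }
    dimer <- make_swapped_dimer(mono)
    return(list(structure = dimer, monomer = mono$structure,
                generated = TRUE, domains = mono$domains,
                annotation = mono$annotation))
  }
  stop("a structure entry needs either $path or $fixture")
}

#' Run the full comparative analysis
#'
#' @param config an [analysis_config].
#' @return list of class `analysis_report` with `results` (per stage),
#'   `errors` (per failed/skipped stage) and `provenance`.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list(results = list(), errors = list(),
                 provenance = list(config_hash = config_hash(config),
                                   package_version = tryCatch(
                                     as.character(utils::packageVersion("swapbp")),
                                     error = function(e) "dev"),
                                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  apo <- tryCatch(load_or_build(config$apo), error = function(e) NULL)
  holo <- tryCatch({
    if (is.null(config$holo) && !is.null(apo) && isTRUE(apo$generated))
      load_or_build(config$apo, closure_angle = config$closure_angle)
    else load_or_build(config$holo)
  }, error = function(e) NULL)
  if (is.null(apo)) {
    report$errors$load_apo <- "apo structure could not be loaded or built"
  }
  if (is.null(holo)) report$errors$load_holo <- "holo structure missing; holo stages skipped"

  doms <- if (!is.null(apo) && !is.null(apo$domains)) apo$domains else {
    list(lobe1 = domain_def("lobe I", config$domains$lobe1),
         lobe2 = domain_def("lobe II", config$domains$lobe2))
  }
  ann <- if (!is.null(apo) && !is.null(apo$annotation)) apo$annotation else
    swap_annotation(config$domains$swapped, config$domains$hinge,
                    config$domains$main_body)
  cuts <- config$cutoffs

  if (!is.null(apo)) {
    report <- stage(report, "rmsd_apo_chains", {
      ch <- chain_ids(apo$structure)
      if (length(ch) >= 2)
        as.numeric(rmsd_structures(apo$structure, apo$structure,
                                   chainA = ch[1], chainB = ch[2]))
      else NA_real_
    })
    report <- stage(report, "closure_apo_chains", {
      ch <- chain_ids(apo$structure)
      cl <- closure_analysis(apo$structure, apo$structure, doms$lobe1,
                             doms$lobe2, chainA = ch[1], chainB = ch[2])
      list(angle = cl$angle, axis = cl$axis, fixed_rmsd = cl$fixed_rmsd,
           moving_rmsd = cl$moving_rmsd)
    })
    report <- stage(report, "interface_apo", {
      ch <- chain_ids(apo$structure)
      ia <- buried_area(apo$structure, ch[1], ch[2],
                        probe = config$sasa$probe,
                        n_points = config$sasa$n_points)
      list(buried_total = ia$buried_total, per_side = ia$buried_per_side,
           interface_area = ia$interface_area,
           n_interface_residues = nrow(ia$interface_residues))
    })
    report <- stage(report, "contacts_apo", {
      contacts <- rbind(
        salt_bridges(apo$structure, cuts$salt_bridge, scope = "inter"),
        hydrogen_bonds(apo$structure, cuts$hbond_dmax, cuts$hbond_angle,
                       scope = "inter"),
        hydrophobic_contacts(apo$structure, cuts$hydrophobic,
                             scope = "inter"))
      cls <- classify_swap_interfaces(apo$structure, ann, contacts)
      list(contacts = contacts, n_c_interface = nrow(cls$c_interface),
           n_o_interface = nrow(cls$o_interface),
           per_chain_c = cls$per_chain_c_counts)
    })
    report <- stage(report, "salt_bridges_intra_apo", {
      ch <- chain_ids(apo$structure)
      stats::setNames(lapply(ch, function(cc)
        nrow(salt_bridges(get_chain(apo$structure, cc),
                          cuts$salt_bridge, scope = "intra"))), ch)
    })
    report <- stage(report, "stereochemistry_apo", {
      g <- backbone_geometry(apo$structure)
      list(geometry = g,
           ncac_by_ss = ncac_by_ss(g),
           delta_omega_windows = psi_window_stats(g, "delta_omega",
                                                  config$psi_windows),
           theta_c_windows = psi_window_stats(g, "theta_c",
                                              config$psi_windows),
           ncac_windows = psi_window_stats(g, "ncac", config$psi_windows))
    })
  }
  if (!is.null(holo)) {
    report <- stage(report, "rmsd_holo_chains", {
      ch <- chain_ids(holo$structure)
      as.numeric(rmsd_structures(holo$structure, holo$structure,
                                 atom_names = c("N", "CA", "C", "O"),
                                 chainA = ch[1], chainB = ch[2]))
    })
    report <- stage(report, "interface_holo", {
      ch <- chain_ids(holo$structure)
      ia <- buried_area(holo$structure, ch[1], ch[2],
                        probe = config$sasa$probe,
                        n_points = config$sasa$n_points)
      list(buried_total = ia$buried_total, per_side = ia$buried_per_side,
           interface_area = ia$interface_area)
    })
    report <- stage(report, "contacts_holo", {
      cls <- classify_swap_interfaces(holo$structure, ann)
      list(n_c_interface = nrow(cls$c_interface),
           n_o_interface = nrow(cls$o_interface))
    })
  }
  if (!is.null(apo) && !is.null(holo)) {
    report <- stage(report, "rmsd_apo_vs_holo", {
      chA <- chain_ids(apo$structure); chH <- chain_ids(holo$structure)
      full <- as.numeric(rmsd_structures(apo$structure, holo$structure,
                                         chainA = chA[1], chainB = chH[1]))
      l1 <- as.numeric(rmsd_structures(apo$structure, holo$structure,
                                       selection = doms$lobe1,
                                       chainA = chA[1], chainB = chH[1]))
      l2 <- as.numeric(rmsd_structures(apo$structure, holo$structure,
                                       selection = doms$lobe2,
                                       chainA = chA[1], chainB = chH[1]))
      list(full_chain = full, lobe1 = l1, lobe2 = l2)
    })
    report <- stage(report, "closure_apo_vs_holo", {
      chA <- chain_ids(apo$structure); chH <- chain_ids(holo$structure)
      out <- list()
      for (ca in chA) {
        cl <- closure_analysis(apo$structure, holo$structure, doms$lobe1,
                               doms$lobe2, chainA = ca, chainB = chH[1])
        out[[paste0("apo_", ca)]] <- list(angle = cl$angle,
                                          fixed_rmsd = cl$fixed_rmsd,
                                          moving_rmsd = cl$moving_rmsd)
      }
      out
    })
    report <- stage(report, "ligand_pocket_holo", {
      lp <- ligand_pocket_contacts(holo$structure,
                                   ligand_resid = config$ligand$resid,
                                   sb_cutoff = cuts$salt_bridge,
                                   hb_dmax = cuts$hbond_dmax,
                                   phob_cutoff = cuts$hydrophobic,
                                   probe = config$sasa$probe,
                                   n_points = config$sasa$n_points)
      list(n_contacts = nrow(lp$contacts), ligand_sasa = lp$ligand_sasa,
           ligand_sasa_free = lp$ligand_sasa_free)
    })
  }
  report <- stage(report, "sequence_metrics", {
    seqrec <- if (!is.null(config$sequence)) {
      sequence_record(config$sequence$one_letter,
                      config$sequence$first_number %||% 1L)
    } else if (!is.null(apo)) {
      sq <- structure_sequence(apo$structure)
      sequence_record(gsub("X", "A", sq$one_letter), sq$first_number)
    } else stop("no sequence available")
    comp <- composition(seqrec)
    mass <- theoretical_mass(seqrec)
    res <- list(pct_charged = comp$pct_charged, pct_polar = comp$pct_polar,
                length = comp$length, monomer_mass_da = mass)
    if (!is.null(config$measured_masses_kda)) {
      res$stoichiometry <- lapply(config$measured_masses_kda,
                                  stoichiometry, monomer_mass_da = mass)
    }
    hr <- config$domains$hinge
    first <- seqrec$first_number
    last <- first + comp$length - 1L
    if (hr[1] >= first && hr[2] <= last)
      res$hinge <- hinge_motif_check(seqrec, hr)
    res
  })
  if (!is.null(config$itc)) {
    report <- stage(report, "itc_fit", {
      des <- config$itc$design %||% itc_design()
      heats <- config$itc$heats
      if (is.null(heats) && !is.null(config$itc$heats_path))
        heats <- read_isotherm_heats(config$itc$heats_path)
      if (is.null(heats)) stop("itc config needs $heats or $heats_path")
      f <- fit_one_site(heats, des)
      if (is.null(f$params)) list(converged = FALSE,
                                  no_binding = f$no_binding)
      else list(n = f$params$n, k_d = f$params$k_d, dh = f$params$dh,
                q_offset = f$params$q_offset, converged = f$converged,
                no_binding = f$no_binding, se = as.list(f$se))
    })
  }
  class(report) <- "analysis_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report to disk
#'
#' Emits `report.json` (structured), `report.txt` (human-readable summary),
#' and, when present in the report, `contacts.tsv` and `geometry.tsv`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  ser <- report
  contacts <- ser$results$contacts_apo$contacts
  geometry <- ser$results$stereochemistry_apo$geometry
  ser$results$contacts_apo$contacts <- NULL
  ser$results$stereochemistry_apo$geometry <- NULL
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(ser), jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, jp)
  if (!is.null(contacts)) {
    cp <- file.path(dir, "contacts.tsv")
    utils::write.table(contacts, cp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, cp)
  }
  if (!is.null(geometry)) {
    gp <- file.path(dir, "geometry.tsv")
    utils::write.table(geometry, gp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, gp)
  }
  tp <- file.path(dir, "report.txt")
  con <- file(tp, "w")
  sink(con)
  cat("Comparative swapped-dimer analysis report\n")
  cat("=========================================\n")
  cat("config hash:", report$provenance$config_hash, "\n\n")
  str(report$results, max.level = 2, give.attr = FALSE)
  if (length(report$errors)) {
    cat("\nStage errors / skips:\n")
    for (nm in names(report$errors)) cat(" -", nm, ":", report$errors[[nm]], "\n")
  }
  sink()
  close(con)
  paths <- c(paths, tp)
  invisible(paths)
}
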