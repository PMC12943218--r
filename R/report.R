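# Report builders mirroring the campaign's summary-table layouts:
# an affinity ranking, per-compound interaction lists, the descriptor/ADMET
# table, the reactivity table, and the assay (IC50 / FRAP / ANOVA) report.

write_report_tables <- function(bundle, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    obj <- bundle[[nm]]
    if (is.data.frame(obj)) {
      readr::write_csv(obj, file.path(out_dir, paste0(nm, ".csv")))
    } else if (nm == "manifest") {
      jsonlite::write_json(obj, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  invisible(NULL)
}

run_stage <- function(manifest, name, expr) {
  res <- tryCatch(list(value = force(expr), status = "ok"),
    error = function(e) list(value = NULL,
      status = paste0("failed: ", conditionMessage(e))))
  manifest$stages[[name]] <- res$status
  list(value = res$value, manifest = manifest)
}

#' Build the structure-based screening report
#'
#' Orchestrates the docking post-processing stages and emits the
#' campaign-style summary tables: an affinity ranking (most favourable
#' first), per-compound interaction residue lists, the descriptor/ADMET
#' table, and the reactivity table, plus a manifest recording package
#' version, parameters and per-stage status. Stages with missing inputs
#' are skipped; a failing stage is marked failed while the others are
#' still emitted.
#'
#' @param poses Named list (compound -> pose tibble from
#'   [read_pdbqt_poses()] or PDBQT file path), or a tibble with columns
#'   `compound`, `affinity` (pre-extracted affinities). `NULL` to skip.
#' @param complexes Named list (compound -> `complex_structure` or PDB
#'   path) for interaction profiling. `NULL` to skip.
#' @param compounds Input for [build_admet_table()] (fixture names, SMILES,
#'   or a data frame); `NULL` to skip.
#' @param orbitals Input for [build_reactivity_table()]; `NULL` to skip.
#' @param criteria An [interaction_criteria()] object.
#' @param angle_mode,strict_pi Profiler mode switches.
#' @param out_dir Optional directory for CSV/JSON output.
#' @return A list with `affinity_table`, `interaction_table`,
#'   `admet_table`, `reactivity_table`, `manifest`.
#' @export
run_screening_report <- function(poses = NULL, complexes = NULL,
                                 compounds = NULL, orbitals = NULL,
                                 criteria = interaction_criteria(),
                                 angle_mode = FALSE, strict_pi = FALSE,
                                 out_dir = NULL) {
  manifest <- list(
    package = "flavoscreen",
    version = as.character(utils::packageVersion("flavoscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    criteria = unclass(criteria),
    angle_mode = angle_mode, strict_pi = strict_pi,
    stages = list()
  )

  st <- run_stage(manifest, "affinity_ranking", {
    if (is.null(poses)) {
      NULL
    } else if (is.data.frame(poses)) {
      dplyr::mutate(dplyr::arrange(poses, .data$affinity),
        rank = dplyr::row_number())
    } else {
      best <- purrr::imap_dfr(poses, function(p, nm) {
        if (is.character(p)) p <- read_pdbqt_poses(p)
        sel <- select_best_pose(p)
        tibble::tibble(compound = nm, affinity = sel$affinity,
          pose_rank = sel$rank)
      })
      dplyr::mutate(dplyr::arrange(best, .data$affinity),
        rank = dplyr::row_number())
    }
  })
  manifest <- st$manifest
  affinity_table <- st$value
  if (is.null(poses)) manifest$stages$affinity_ranking <- "skipped (no poses)"

  st <- run_stage(manifest, "interaction_profiling", {
    if (is.null(complexes)) {
      NULL
    } else {
      purrr::imap_dfr(complexes, function(cx, nm) {
        if (is.character(cx)) cx <- read_pdb(cx, ligand_name = nm)
        pr <- profile_complex(cx, criteria, angle_mode = angle_mode,
          strict_pi = strict_pi)
        fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "-"
        tibble::tibble(
          compound = nm,
          hbond_residues = fmt(pr$hbond_residues),
          pistack_residues = fmt(pr$pistack_residues),
          hydrophobic_contacts = fmt(pr$hydrophobic_residues)
        )
      })
    }
  })
  manifest <- st$manifest
  interaction_table <- st$value
  if (is.null(complexes)) {
    manifest$stages$interaction_profiling <- "skipped (no complexes)"
  }

  st <- run_stage(manifest, "admet", {
    if (is.null(compounds)) NULL else build_admet_table(compounds)
  })
  manifest <- st$manifest
  admet_table <- st$value
  if (is.null(compounds)) manifest$stages$admet <- "skipped (no compounds)"

  st <- run_stage(manifest, "reactivity", {
    if (is.null(orbitals)) NULL else build_reactivity_table(orbitals)
  })
  manifest <- st$manifest
  reactivity_table <- st$value
  if (is.null(orbitals)) manifest$stages$reactivity <- "skipped (no orbitals)"

  bundle <- list(
    affinity_table = affinity_table,
    interaction_table = interaction_table,
    admet_table = admet_table,
    reactivity_table = reactivity_table,
    manifest = manifest
  )
  write_report_tables(bundle, out_dir)
  bundle
}

#' Build the antioxidant assay report
#'
#' Fits a four-parameter logistic curve per compound and assay, reports
#' IC50 +/- SD (replicate refits) and r-squared in the campaign's summary
#' layout, optionally adds a FRAP Trolox-equivalent column, and runs a
#' one-way ANOVA with Tukey HSD across compounds on the replicate IC50
#' estimates when at least two compounds provide them.
#'
#' @param dose_data A tibble with columns `compound`, `concentration`,
#'   `replicate`, `activity` (one assay), e.g. rows from
#'   [gen_dose_response()]; may be empty.
#' @param frap_standards Optional standards for
#'   [frap_trolox_equivalents()].
#' @param frap_samples Optional tibble with `compound`, `absorbance` and
#'   optionally `mass_factor`.
#' @param out_dir Optional directory for CSV/JSON output.
#' @return A list with `ic50_table`, `frap_table`, `anova` (an
#'   `anova_tukey` or `NULL`), `notes` (character), `manifest`.
#' @export
run_assay_report <- function(dose_data, frap_standards = NULL,
                             frap_samples = NULL, out_dir = NULL) {
  manifest <- list(
    package = "flavoscreen",
    version = as.character(utils::packageVersion("flavoscreen")),
    stages = list()
  )
  notes <- character(0)
  empty_tbl <- tibble::tibble(compound = character(), ic50 = double(),
    ic50_sd = double(), r_squared = double())
  if (is.null(dose_data) || nrow(dose_data) == 0) {
    warn("No dose-response data supplied; emitting header-only IC50 table.")
    manifest$stages$ic50 <- "skipped (no data)"
    bundle <- list(ic50_table = empty_tbl, frap_table = NULL, anova = NULL,
      notes = "no dose-response data", manifest = manifest)
    write_report_tables(bundle, out_dir)
    return(bundle)
  }
  fits <- list()
  rows <- purrr::map_dfr(unique(dose_data$compound), function(cmp) {
    sub <- dose_data[dose_data$compound == cmp, ]
    f <- tryCatch(fit_four_pl(sub), error = function(e) e)
    if (inherits(f, "error")) {
      notes <<- c(notes, paste0(cmp, ": fit failed (", conditionMessage(f), ")"))
      return(tibble::tibble(compound = cmp, ic50 = NA_real_,
        ic50_sd = NA_real_, r_squared = NA_real_))
    }
    fits[[cmp]] <<- f
    tibble::tibble(compound = cmp, ic50 = f$ic50, ic50_sd = f$ic50_sd,
      r_squared = f$r_squared)
  })
  manifest$stages$ic50 <- "ok"

  frap_table <- NULL
  if (!is.null(frap_standards) && !is.null(frap_samples)) {
    frap_table <- purrr::map_dfr(seq_len(nrow(frap_samples)), function(i) {
      mf <- if ("mass_factor" %in% names(frap_samples)) {
        frap_samples$mass_factor[i]
      } else 1
      res <- frap_trolox_equivalents(frap_standards,
        frap_samples$absorbance[i], mass_factor = mf)
      tibble::tibble(compound = frap_samples$compound[i],
        frap_te_per_g = res$te_per_gram, calibration_r2 = res$r_squared)
    })
    manifest$stages$frap <- "ok"
  } else {
    manifest$stages$frap <- "skipped (no FRAP inputs)"
  }

  anova_res <- NULL
  rep_ic50 <- purrr::imap_dfr(fits, function(f, cmp) {
    if (is.null(f$replicate_ic50)) return(tibble::tibble())
    tibble::tibble(group = cmp, value = f$replicate_ic50[!is.na(f$replicate_ic50)])
  })
  if (nrow(rep_ic50) > 0 && dplyr::n_distinct(rep_ic50$group) >= 2 &&
    all(table(rep_ic50$group) >= 2)) {
    anova_res <- tryCatch(anova_tukey(rep_ic50), error = function(e) {
      notes <<- c(notes, paste0("ANOVA failed: ", conditionMessage(e)))
      NULL
    })
    manifest$stages$anova <- if (is.null(anova_res)) "failed" else "ok"
  } else {
    notes <- c(notes, "ANOVA skipped: needs >= 2 compounds with replicate fits")
    manifest$stages$anova <- "skipped"
  }

  bundle <- list(ic50_table = rows, frap_table = frap_table,
    anova = anova_res, notes = notes, manifest = manifest)
  write_report_tables(bundle[c("ic50_table", "frap_table", "manifest")], out_dir)
  bundle
}
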