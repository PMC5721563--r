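# End-to-end study workflow: load or simulate valve data, superimpose,
# average replicates, build species means, then run the comparative
# analyses (phylogenetic PLS integration overall and per ecomorph,
# directional asymmetry and its D-PGLS on ecomorph, and the four
# evolutionary-rate hypotheses with bootstrap CIs), writing a deterministic
# CSV/JSON report bundle.

stage_seed <- function(seed, offset) as.integer(seed + offset * 101)

run_stage <- function(report, name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir))
      writeLines(c(paste("FAILED at stage:", name), conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full valve-shape study workflow
#'
#' Executes, in order: data loading or generation, pruning of tree and data
#' to shared species, per-valve generalised Procrustes alignment with
#' sliding, replicate averaging, species means, phylogenetic two-block PLS
#' overall and per ecomorph (groups with at least `min_group_pls` species)
#' with pairwise effect-size comparison, joint mirrored superimposition and
#' the directional-asymmetry table, D-PGLS of species asymmetry on
#' ecomorph, the four rate hypotheses (asymmetry rates among ecomorphs;
#' left vs right valve rates across species; per-valve rates among
#' ecomorphs; left vs right within each ecomorph) and bootstrap confidence
#' intervals, and finally an optional CSV/JSON report bundle.
#'
#' A single global seed fans out to fixed per-stage streams so stages are
#' individually reproducible. With `mode = "estimates"` all permutation,
#' simulation and bootstrap machinery is skipped and only point estimates
#' are reported (useful for large simulation studies over many seeds).
#'
#' @param data List with `left`, `right` ([specimen_set()]s) and `tree`, or
#'   `NULL` to generate from `generator`.
#' @param generator A [generator_config()] used when `data` is `NULL`.
#' @param n_perm,n_sim,n_boot Resampling sizes (each >= 99; the study
#'   design uses 1000 throughout).
#' @param seed Integer seed (mandatory).
#' @param out_dir Optional output directory for the report bundle.
#' @param mode `"full"` or `"estimates"` (point estimates only).
#' @param slide Slide semilandmarks during superimpositions (default
#'   `TRUE`).
#' @param min_group_pls Minimum species for a per-ecomorph PLS (default 4).
#' @param min_group_rate Minimum species for a within-group rate test
#'   (default 2; smaller groups get flagged point estimates).
#' @return A `valve_study` report list; see the elements `pls`,
#'   `asymmetry`, `pgls`, `rates`, `bootstrap`, `pattern`, `manifest`.
#' @export
run_study <- function(data = NULL, generator = NULL,
                      n_perm = 1000, n_sim = 1000, n_boot = 1000,
                      seed = 1L, out_dir = NULL,
                      mode = c("full", "estimates"), slide = TRUE,
                      min_group_pls = 4, min_group_rate = 2) {
  mode <- match.arg(mode)
  if (is.null(seed)) stop("seed is mandatory")
  full <- mode == "full"
  if (full && (n_perm < 99 || n_sim < 99 || n_boot < 99))
    stop("n_perm, n_sim and n_boot must each be >= 99")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  report <- list(seed = seed, mode = mode)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
    message(sprintf("[%s] done (%.1fs)", name, timings[[name]]))
  }

  run_stage(report, "data", out_dir, {
    if (is.null(data)) {
      if (is.null(generator)) generator <- generator_config(seed = seed)
      data <- generate_dataset(generator)
      report$generator <- generator
    }
  })
  tick("data")

  run_stage(report, "prune", out_dir, {
    species_all <- union(unique(data$left$labels$species),
                         unique(data$right$labels$species))
    pl <- prune_to_common(data$tree, data$left)
    pr <- list(tree = pl$tree,
               data = subset_specimens(
                 data$right,
                 which(data$right$labels$species %in% pl$species)))
    tree <- pl$tree
    species <- pl$species
    left <- pl$data
    right <- pr$data
  })
  tick("prune")

  run_stage(report, "gpa", out_dir, {
    aligned_left <- gpa_align(left, slide = slide)
    aligned_right <- gpa_align(right, slide = slide)
    avg_left <- average_replicates(aligned_left)
    avg_right <- average_replicates(aligned_right)
    means_left <- species_means(avg_left, species)
    means_right <- species_means(avg_right, species)
    YL <- shape_matrix(means_left)
    YR <- shape_matrix(means_right)
    C <- phylo_covariance(tree, species)
    groups <- setNames(left$labels$ecomorph[
      match(species, left$labels$species)], species)
    report$n_species <- length(species)
    report$n_specimens <- length(unique(c(left$labels$specimen_id,
                                          right$labels$specimen_id)))
    report$converged <- c(left = aligned_left$converged,
                          right = aligned_right$converged)
  })
  tick("gpa")

  run_stage(report, "integration", out_dir, {
    if (full) {
      pls_all <- pls_permutation(YL, YR, C, n_perm = n_perm,
                                 seed = stage_seed(seed, 1))
      eco_tab <- table(groups)
      eligible <- names(eco_tab)[eco_tab >= min_group_pls]
      pls_eco <- list()
      for (g in eligible) {
        idx <- which(groups == g)
        pls_eco[[g]] <- pls_permutation(YL[idx, , drop = FALSE],
                                        YR[idx, , drop = FALSE],
                                        C[idx, idx, drop = FALSE],
                                        n_perm = n_perm,
                                        seed = stage_seed(seed, 2))
      }
      pls_compare <- if (length(pls_eco) >= 2) compare_pls_effects(pls_eco)
      report$pls <- list(all = pls_all, by_ecomorph = pls_eco,
                         comparison = pls_compare)
    } else {
      report$pls <- list(all = phylo_pls(YL, YR, C))
    }
  })
  tick("integration")

  run_stage(report, "asymmetry", out_dir, {
    joint <- joint_superimpose(left, right, slide = slide)
    joint_avg <- average_replicates(joint)
    da <- asymmetry_magnitude(joint_avg, average_replicates = FALSE)
    da_species <- matrix(da$species$da_mean[match(species, da$species$species)],
                         ncol = 1, dimnames = list(species, "da"))
    report$asymmetry <- list(table = da,
                             by_ecomorph = asymmetry_by_ecomorph(da))
  })
  tick("asymmetry")

  run_stage(report, "pgls", out_dir, {
    report$pgls <- if (full)
      dpgls_permutation(da_species, groups, C, n_perm = n_perm,
                        seed = stage_seed(seed, 3))
    else dpgls_fit(da_species, groups, C)
  })
  tick("pgls")

  run_stage(report, "rates", out_dir, {
    if (full) {
      h1 <- compare_rates_groups(da_species, groups, C, n_sim = n_sim,
                                 seed = stage_seed(seed, 4))
      h2 <- compare_rates_traits(list(left = YL, right = YR), C,
                                 n_sim = n_sim, seed = stage_seed(seed, 5))
      h3_left <- compare_rates_groups(YL, groups, C, n_sim = n_sim,
                                      seed = stage_seed(seed, 6))
      h3_right <- compare_rates_groups(YR, groups, C, n_sim = n_sim,
                                       seed = stage_seed(seed, 7))
      h4 <- rates_within_groups(YL, YR, groups, C, n_sim = n_sim,
                                seed = stage_seed(seed, 8))
    } else {
      pt_da <- phylo_transform(da_species, C)
      h1 <- list(sigma2 = group_sigma2(pt_da$U, factor(groups), 1))
      ptL <- phylo_transform(YL, C)
      ptR <- phylo_transform(YR, C)
      sL <- sum(ptL$U^2) / (nrow(YL) * ncol(YL))
      sR <- sum(ptR$U^2) / (nrow(YR) * ncol(YR))
      h2 <- list(sigma2 = c(left = sL, right = sR), ratio = max(sL, sR) / min(sL, sR))
      h3_left <- list(sigma2 = group_sigma2(ptL$U, factor(groups), ncol(YL)))
      h3_right <- list(sigma2 = group_sigma2(ptR$U, factor(groups), ncol(YR)))
      h4 <- NULL
    }
    report$rates <- list(da_groups = h1, valves = h2, left_groups = h3_left,
                         right_groups = h3_right, within_groups = h4)
  })
  tick("rates")

  if (full) {
    run_stage(report, "bootstrap", out_dir, {
      boot_stat_valves <- function(avg_set, side_label) {
        force(avg_set)
        function(s) {
          mm <- shape_matrix(species_means(s, species))
          pt <- phylo_transform(mm, C)
          grp <- group_sigma2(pt$U, factor(groups[rownames(mm)]), pt$p)
          c(setNames(sum(pt$U^2) / (nrow(mm) * pt$p), side_label),
            setNames(grp, paste0(side_label, ".", names(grp))))
        }
      }
      set.seed(stage_seed(seed, 9))
      bootL <- bootstrap_rate_ci(avg_left, boot_stat_valves(avg_left, "left"),
                                 n_boot = n_boot)
      bootR <- bootstrap_rate_ci(avg_right, boot_stat_valves(avg_right, "right"),
                                 n_boot = n_boot)
      da_stat <- function(s) {
        tab <- asymmetry_magnitude(s, average_replicates = FALSE)
        dam <- matrix(tab$species$da_mean[match(species, tab$species$species)],
                      ncol = 1, dimnames = list(species, "da"))
        pt <- phylo_transform(dam, C)
        grp <- group_sigma2(pt$U, factor(groups), 1)
        c(da = sum(pt$U^2) / nrow(dam), setNames(grp, paste0("da.", names(grp))))
      }
      bootDA <- bootstrap_rate_ci(joint_avg, da_stat, n_boot = n_boot)
      report$bootstrap <- list(left = bootL$ci, right = bootR$ci,
                               da = bootDA$ci, n_boot = n_boot)
    })
    tick("bootstrap")
  }

  report$pattern <- study_pattern(report)
  report$timings <- timings
  report$manifest <- list(package = "valvemorph",
                          version = as.character(utils::packageVersion("valvemorph")),
                          seed = seed, mode = mode,
                          n_perm = if (full) n_perm else 0,
                          n_sim = if (full) n_sim else 0,
                          n_boot = if (full) n_boot else 0,
                          n_species = report$n_species)
  class(report) <- "valve_study"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Qualitative rate/asymmetry pattern of a study report
#'
#' Summarises the study's headline qualitative findings as logicals:
#' whether the right valve's overall rate exceeds the left's, whether the
#' gliding/recessing/nestling ecomorphs occupy the top three right-valve
#' rates, whether byssal-attaching is the (or second-) slowest right-valve
#' ecomorph, and whether recessing species show the highest mean asymmetry
#' with gliding among the lowest.
#'
#' @param report A `valve_study` from [run_study()].
#' @return List of logicals plus `all` (their conjunction).
#' @export
study_pattern <- function(report) {
  h2 <- report$rates$valves$sigma2
  right_gt_left <- unname(h2[["right"]] > h2[["left"]])
  sr <- sort(report$rates$right_groups$sigma2, decreasing = TRUE)
  trio <- c("gliding", "recessing", "nestling")
  trio_top3 <- all(trio %in% names(sr)[1:3])
  byssal_rank <- match("byssal-attaching", names(sort(sr)))
  byssal_low <- !is.na(byssal_rank) && byssal_rank <= 2
  eco <- report$asymmetry$by_ecomorph
  da_ord <- eco$ecomorph[order(eco$da_mean, decreasing = TRUE)]
  recess_highest_da <- length(da_ord) > 0 && da_ord[1] == "recessing"
  list(right_gt_left = right_gt_left, trio_top3 = trio_top3,
       byssal_low = byssal_low, recess_highest_da = recess_highest_da,
       all = right_gt_left && trio_top3 && byssal_low)
}

#' @export
print.valve_study <- function(x, ...) {
  cat("valve-shape study report (seed ", x$seed, ", mode ", x$mode, ")\n",
      sep = "")
  cat(sprintf("  %d species; rPLS(all) = %.3f\n", x$n_species,
              x$pls$all$r_pls))
  h2 <- x$rates$valves
  cat(sprintf("  sigma2 left = %.3g, right = %.3g (ratio %.3g)\n",
              h2$sigma2[["left"]], h2$sigma2[["right"]], h2$ratio))
  cat("  pattern: ", paste(names(which(unlist(x$pattern))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write the CSV/JSON report bundle of a study
#'
#' Every number written is taken from the report object (no computation in
#' the reporting layer). The manifest records seed, package version,
#' resampling sizes and MD5 hashes of all emitted CSVs, making a run's
#' output hash-comparable.
#'
#' @param report A `valve_study`.
#' @param out_dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  pls_rows <- list(data.frame(label = "all", n = report$pls$all$n,
                              r_pls = report$pls$all$r_pls,
                              z = report$pls$all$z_score %||% NA,
                              p = report$pls$all$p_value %||% NA,
                              n_perm = report$pls$all$n_perm %||% 0))
  for (g in names(report$pls$by_ecomorph)) {
    r <- report$pls$by_ecomorph[[g]]
    pls_rows[[g]] <- data.frame(label = g, n = r$n, r_pls = r$r_pls,
                                z = r$z_score, p = r$p_value,
                                n_perm = r$n_perm)
  }
  wcsv(do.call(rbind, pls_rows), "pls.csv")
  if (!is.null(report$pls$comparison)) {
    cmp <- report$pls$comparison
    wcsv(data.frame(label = rownames(cmp$p), cmp$p, check.names = FALSE),
         "pls_pairwise_p.csv")
  }
  wcsv(report$asymmetry$table$specimens, "asymmetry_specimens.csv")
  wcsv(report$asymmetry$table$species, "asymmetry_species.csv")
  wcsv(report$asymmetry$by_ecomorph, "asymmetry_ecomorphs.csv")
  pg <- report$pgls
  wcsv(data.frame(effect = "ecomorph", df = pg$df_model,
                  df_resid = pg$df_resid, ss = pg$ss_model,
                  ss_resid = pg$ss_resid, f = pg$f_stat,
                  p = pg$p_value), "pgls.csv")
  rate_rows <- list()
  add_rates <- function(hyp, rr) {
    if (is.null(rr)) return()
    rate_rows[[hyp]] <<- data.frame(
      hypothesis = hyp, label = names(rr$sigma2),
      sigma2 = unname(rr$sigma2),
      ratio = rr$ratio %||% NA, p = rr$p_value %||% NA,
      n_sim = rr$n_sim %||% 0)
  }
  add_rates("da_groups", report$rates$da_groups)
  add_rates("valves", report$rates$valves)
  add_rates("left_groups", report$rates$left_groups)
  add_rates("right_groups", report$rates$right_groups)
  wcsv(do.call(rbind, rate_rows), "rates.csv")
  if (!is.null(report$rates$within_groups))
    wcsv(report$rates$within_groups$summary, "rates_within_groups.csv")
  for (h in c("da_groups", "left_groups", "right_groups")) {
    pw <- report$rates[[h]]$pairwise_p
    if (!is.null(pw))
      wcsv(data.frame(label = rownames(pw), pw, check.names = FALSE),
           paste0("rates_pairwise_", h, ".csv"))
  }
  if (!is.null(report$bootstrap)) {
    boot <- rbind(report$bootstrap$left, report$bootstrap$right,
                  report$bootstrap$da)
    wcsv(boot, "bootstrap_ci.csv")
  }
  manifest <- report$manifest
  manifest$pattern <- report$pattern
  manifest$files <- as.list(tools::md5sum(unlist(paths)))
  names(manifest$files) <- names(paths)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  paths[["manifest.json"]] <- mp
  invisible(unlist(paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
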