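#' Run the full selective-regime analysis
#'
#' Orchestrates the whole chain on one gene: sequence integrity screening
#' (pseudogene exclusion), optional precursor split into cleaved and mature
#' domains, the clade-model suite with the positive-selection/relaxation
#' decision, the site-model suite with BEB site classification and
#' functional-domain profiling, the free-ratio fit with root-to-tip omega per
#' species, and the pGLS of root-to-tip omega against relative testes mass.
#' Every stage failure is re-thrown with a stage label; outputs written so
#' far are preserved.
#'
#' @param config a named list or path to a YAML file. Recognised fields:
#'   `alignment` (FASTA path or `codon_alignment`), `gene`, `site_tree`,
#'   `clade_tree` (Newick paths or `phylo`), `foreground` (tips),
#'   `traits` (TSV path with species / body_mass_g / testes_mass_g or a
#'   data.frame), `allometry` (list `a`, `b`), `prm2_boundary` (cleaved-domain
#'   codon count or NULL), `kinases`, `cleavage_sites` + `reference`,
#'   `identity_floor`, `freq_model`, `K`, `branch_mode`, `include_stem`,
#'   `cleandata`, `alpha` (significance level), `flank_window`, `seed`,
#'   `out_dir`, `force_include` (taxa never excluded), `stages` (subset of
#'   `c("integrity", "clade", "site", "roottip", "pgls")`).
#' @return Invisibly, a list of stage results (also written as TSV/JSON
#'   under `out_dir` when given).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dflt <- list(gene = "gene", freq_model = "F3X4", K = 10,
               branch_mode = "free", include_stem = TRUE, cleandata = TRUE,
               alpha = 0.05, flank_window = 5, identity_floor = 30,
               kinases = c("PKC", "PKA", "CK2"), seed = 1,
               force_include = character(0),
               stages = c("integrity", "clade", "site", "roottip", "pgls"))
  config <- utils::modifyList(dflt, config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  emit <- function(obj, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    if (grepl("\\.json$", file)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    } else {
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    invisible(path)
  }

  res <- list(config = config)
  aln <- stage("input", {
    a <- config$alignment
    if (is.character(a)) read_fasta(a, config$gene) else a
  })
  site_tree <- stage("input", {
    tt <- config$site_tree
    if (is.character(tt)) ape::read.tree(tt) else tt
  })
  clade_tree <- if (!is.null(config$clade_tree)) stage("input", {
    tt <- config$clade_tree
    if (is.character(tt)) ape::read.tree(tt) else tt
  }) else site_tree

  # -- integrity screen: flag pseudogenized sequences, exclude them --------
  if ("integrity" %in% config$stages) {
    res$integrity <- stage("integrity", {
      rows <- lapply(aln$taxa, function(tx) {
        nt <- gsub("-", "", paste0(aln$codons[match(tx, aln$taxa), ],
                                   collapse = ""))
        refs <- vapply(setdiff(aln$taxa, tx), function(o) {
          cods <- aln$codons[match(o, aln$taxa), ]
          cods <- cods[!grepl("-", cods)]
          aa <- translate_codons(cods)
          paste0(aa[!is.na(aa) & aa != "*"], collapse = "")
        }, character(1))
        chk <- integrity_check(nt, refs, config$identity_floor)
        data.frame(species = tx, status = chk$status,
                   criteria = paste(chk$criteria, collapse = ";"),
                   best_identity = chk$best_identity)
      })
      do.call(rbind, rows)
    })
    excluded <- setdiff(
      res$integrity$species[res$integrity$status == "dysfunctional"],
      config$force_include)
    res$excluded <- excluded
    if (length(excluded)) {
      aln <- subset_taxa(aln, setdiff(aln$taxa, excluded))
    }
    emit(res$integrity, "integrity.tsv")
  }

  # -- optional precursor split --------------------------------------------
  parts <- list()
  parts[[config$gene]] <- aln
  if (!is.null(config$prm2_boundary)) {
    sp <- stage("split", split_prm2(
      aln, domain_boundary(config$prm2_boundary, n_codons(aln))))
    parts[[paste0(config$gene, "_cleaved")]] <- sp$cleaved
    parts[[paste0(config$gene, "_mature")]] <- sp$mature
  }

  fit_args <- list(freq_model = config$freq_model,
                   branch_mode = config$branch_mode,
                   cleandata = config$cleandata)

  # -- clade analysis -------------------------------------------------------
  if ("clade" %in% config$stages && !is.null(config$foreground)) {
    res$clade <- stage("clade", lapply(parts, function(a) {
      fg <- intersect(config$foreground, a$taxa)
      suite <- do.call(fit_clade_suite, c(
        list(alignment = a, tree = clade_tree, foreground = fg,
             include_stem = config$include_stem), fit_args))
      dec <- classify_clade(suite$m1, suite$m2, suite$m3,
                            alpha = config$alpha)
      list(suite = suite, decision = dec)
    }))
    tab <- do.call(rbind, lapply(names(res$clade), function(g) {
      d <- res$clade[[g]]$decision
      data.frame(gene = g, foreground_omega = d$foreground_omega,
                 lrt13_2dl = d$lrt_m1_vs_m3$two_delta_l,
                 lrt13_p = d$lrt_m1_vs_m3$p_value,
                 lrt23_2dl = d$lrt_m2_vs_m3$two_delta_l,
                 lrt23_p = d$lrt_m2_vs_m3$p_value,
                 label = d$label)
    }))
    res$clade_table <- tab
    emit(tab, "clade_decisions.tsv")
  }

  # -- site analysis + domains ---------------------------------------------
  if ("site" %in% config$stages) {
    res$site <- stage("site", lapply(parts, function(a) {
      suite <- do.call(fit_site_suite,
                       c(list(alignment = a, tree = site_tree, K = config$K),
                         fit_args))
      cls_fit <- if (grepl("M2a", suite$designation)) suite$fits$M2a
                 else suite$fits$M1a
      post <- beb_classify(a, site_tree, cls_fit)
      ref <- config$reference
      if (is.null(ref) || !ref %in% a$taxa) ref <- a$taxa[1]
      refrow <- a$codons[match(ref, a$taxa), ]
      aa <- translate_codons(ifelse(grepl("-", refrow), "NNN", refrow))
      aa[is.na(aa)] <- "X"
      prot <- paste0(aa, collapse = "")
      ann <- rbind(scan_anchoring(prot, config$flank_window),
                   scan_phospho(prot, config$kinases))
      if (!is.null(config$cleavage_sites) &&
          identical(a$gene_label, grep("cleaved", names(parts),
                                       value = TRUE)[1])) {
        ann <- rbind(ann, map_configured_sites(a, config$cleavage_sites,
                                               "cleavage", ref))
      }
      summ <- summarize_site_classes(post, if (nrow(ann)) ann else NULL, aa)
      prof <- if (nrow(ann)) profile_regions(post, ann) else NULL
      list(suite = suite, posterior = post, annotation = ann,
           summary = summ, profile = prof)
    }))
    for (g in names(res$site)) {
      emit(res$site[[g]]$posterior$sites,
           paste0("site_posterior_", g, ".tsv"))
      s <- res$site[[g]]
      emit(list(gene = g, designation = s$suite$designation,
                lnL = lapply(s$suite$fits, function(f) f$lnL),
                lrt_m1a_m2a = s$suite$lrt_m1a_m2a[
                  c("two_delta_l", "df", "p_value", "verdict")],
                lrt_m7_m8 = s$suite$lrt_m7_m8[
                  c("two_delta_l", "df", "p_value", "verdict")],
                overall = as.list(s$summary$overall),
                pss = s$summary$pss),
           paste0("site_summary_", g, ".json"))
    }
  }

  # -- root-to-tip omega ----------------------------------------------------
  if ("roottip" %in% config$stages) {
    res$roottip <- stage("roottip", lapply(parts, function(a) {
      fr <- do.call(free_ratio_fit,
                    c(list(alignment = a, tree = site_tree), fit_args))
      path_omega_table(fr)
    }))
    for (g in names(res$roottip)) {
      emit(res$roottip[[g]], paste0("roottip_", g, ".tsv"))
    }
  }

  # -- comparative ----------------------------------------------------------
  if ("pgls" %in% config$stages && !is.null(config$traits) &&
      !is.null(res$roottip)) {
    res$pgls <- stage("pgls", {
      trt <- config$traits
      if (is.character(trt)) {
        trt <- utils::read.table(trt, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      }
      rtm <- relative_testes_mass(trt$body_mass_g, trt$testes_mass_g,
                                  config$allometry$a, config$allometry$b)
      names(rtm) <- trt$species
      lapply(res$roottip, function(rt) {
        om <- stats::setNames(rt$omega_path, rt$species)
        om <- om[!is.na(om)]
        pgls_fit(site_tree, x = rtm, y = om)
      })
    })
    tab <- do.call(rbind, lapply(names(res$pgls), function(g) {
      f <- res$pgls[[g]]
      data.frame(gene = g, N = f$n, ci_lower = unname(f$ci[1]),
                 ci_upper = unname(f$ci[2]), lnL = f$lnL, alpha = f$alpha,
                 correlation = f$correlation,
                 significance = significance_by_ci(f))
    }))
    rownames(tab) <- NULL
    res$pgls_table <- tab
    emit(tab, "pgls.tsv")
  }

  emit(list(config = config[setdiff(names(config), "alignment")],
            seed = config$seed,
            excluded = res$excluded), "run_config.json")
  invisible(res)
}
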