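#' Run configuration for the analysis pipeline
#'
#' A run is driven by a single configuration so that paired conditions
#' (e.g. with and without a guest amphiphile) stay parameter-locked.
#' Exactly one input source must be given: either `input` (paths to a
#' site-table TSV plus a TRJTXT/GRO trajectory) or `synthetic` (a
#' [bilayer_spec()] argument list plus `n_frames`, `dt_ps`).
#'
#' @param synthetic optional list of [bilayer_spec()] arguments plus
#'   `n_frames` and `dt_ps`.
#' @param input optional list `sites` (TSV path) and `trajectory`
#'   (TRJTXT path) or `gro` (multi-frame GRO path).
#' @param analyses character vector of analyses to run, a subset of
#'   `c("leaflets", "thickness", "apl", "p2", "scd", "density",
#'   "potential", "rdf", "contacts", "msd", "flipflops")`. May be empty.
#' @param params per-analysis parameters: `ref`, `transit_band`,
#'   `n_bins`, `density_weight`, `contact_cutoff`, `guest_groups`,
#'   `lipid_classes`, `rdf_selA`, `rdf_selB`, `rdf_rmax`, `rdf_dr`,
#'   `msd_sel`, `msd_window`, `min_residency_ps`, `chain`, `scd_mode`,
#'   `n_blocks`. Unset entries take package defaults.
#' @param outdir output directory (created if missing).
#' @param seed integer seed overriding the synthetic spec's seed.
#' @return a validated `run_config`.
#' @export
run_config <- function(synthetic = NULL, input = NULL,
                       analyses = c("leaflets", "thickness", "apl", "p2"),
                       params = list(), outdir, seed = 1) {
  if (is.null(synthetic) == is.null(input))
    stop("exactly one of 'synthetic' and 'input' must be given")
  known <- c("leaflets", "thickness", "apl", "p2", "scd", "density",
             "potential", "rdf", "contacts", "msd", "flipflops")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  defaults <- list(ref = "polarity_class == phosphate", transit_band = 0.3,
                   n_bins = 100, density_weight = "mass",
                   contact_cutoff = 0.35,
                   guest_groups = list(
                     carboxylate = "polarity_class == headgroup_carboxylate",
                     hydroxyl = "polarity_class == hydroxyl"),
                   lipid_classes = list(
                     phosphate = "polarity_class == phosphate",
                     amine = "polarity_class == headgroup_amine"),
                   rdf_selA = "polarity_class == phosphate",
                   rdf_selB = "polarity_class == phosphate",
                   rdf_rmax = NA_real_, rdf_dr = 0.02,
                   msd_sel = "polarity_class == phosphate",
                   msd_window = c(0.1, 0.5), min_residency_ps = 10000,
                   chain = "sn1", scd_mode = "reconstructed", n_blocks = 5)
  params <- utils::modifyList(defaults, params)
  structure(list(synthetic = synthetic, input = input,
                 analyses = analyses, params = params, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file path; top-level keys mirror [run_config()]
#'   arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(synthetic = y$synthetic, input = y$input,
             analyses = as.character(y$analyses %||% character()),
             params = y$params %||% list(),
             outdir = y$outdir, seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_input <- function(config) {
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    n_frames <- sy$n_frames %||% 100
    dt <- sy$dt_ps %||% 100
    sy$n_frames <- NULL; sy$dt_ps <- NULL
    sy$seed <- config$seed
    spec <- do.call(bilayer_spec, sy)
    gen <- generate_bilayer_trajectory(spec, n_frames, dt)
    list(sites = gen$sites, traj = gen$trajectory, spec = spec)
  } else {
    sites <- read_site_table(config$input$sites)
    traj <- if (!is.null(config$input$trajectory))
      read_trjtxt(config$input$trajectory, sites)
    else {
      gr <- read_gro(config$input$gro, sites = sites)
      if (!is.null(gr$trajectory)) gr$trajectory
      else as_trajectory(sites, gr$frame)
    }
    list(sites = sites, traj = traj, spec = NULL)
  }
}

#' Run the analysis pipeline
#'
#' Loads or generates the system, validates every referenced selection
#' against the site table before any analysis runs, then executes the
#' requested analyses in dependency order (leaflets, geometry,
#' order/density, contacts/kinetics). Each result is written as a TSV
#' in `outdir`, and a machine-readable `manifest.json` records inputs,
#' parameters, package version, seed, every output file, and a
#' per-analysis status. Identical configuration and seed give
#' byte-identical numeric outputs. A failed analysis is recorded in the
#' manifest (status `failed`) without aborting the remaining analyses;
#' `overall_status` is `failed` iff any requested analysis failed.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inp <- load_pipeline_input(config)
  p <- config$params
  # validate all referenced selections up front
  sels <- c(p$ref, p$rdf_selA, p$rdf_selB, p$msd_sel,
            unlist(p$guest_groups), unlist(p$lipid_classes))
  for (s in sels) select_sites(inp$sites, s)
  status <- list()
  files <- character()
  results <- list()
  emit <- function(name, df, meta = list()) {
    fn <- paste0(name, ".tsv")
    write_result_tsv(df, file.path(config$outdir, fn), meta)
    files <<- c(files, fn)
  }
  run_one <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    status[[name]] <<- if (res$ok) "ok" else paste("failed:", res$msg)
    if (res$ok) results[[name]] <<- res$value
    res
  }
  need_assignment <- any(config$analyses %in%
                           c("leaflets", "thickness", "apl", "msd",
                             "flipflops"))
  assignment <- NULL
  if (need_assignment)
    assignment <- assign_leaflets(inp$traj, p$ref, p$transit_band)
  for (an in config$analyses) {
    run_one(an, switch(an,
      leaflets = function() {
        df <- data.frame(
          time_ps = rep(assignment$times,
                        times = length(assignment$molecule_id)),
          molecule_id = rep(assignment$molecule_id,
                            each = length(assignment$times)),
          label = as.vector(assignment$labels))
        emit("leaflets", df, list(ref = p$ref,
                                  transit_band_nm = p$transit_band))
        assignment
      },
      thickness = function() {
        df <- membrane_thickness(inp$traj, p$ref, p$transit_band)
        emit("thickness", df, list(ref = p$ref))
        df
      },
      apl = function() {
        df <- area_per_lipid(inp$traj, assignment)
        emit("apl", df, list(ref = p$ref))
        df
      },
      p2 = function() {
        bl <- chain_bond_list(inp$sites, p$chain)
        df <- cg_order_p2(inp$traj, bl$bonds, bl$labels, p$n_blocks)
        emit("p2", df, list(chain = p$chain))
        df
      },
      scd = function() {
        df <- deuterium_order_scd(inp$traj, p$chain, p$scd_mode,
                                  p$n_blocks)
        emit("scd", df, list(chain = p$chain, h_mode = p$scd_mode))
        df
      },
      density = function() {
        df <- density_profile(inp$traj, "all", p$density_weight, p$n_bins)
        emit("density", df, list(weight = p$density_weight,
                                 n_bins = p$n_bins))
        df
      },
      potential = function() {
        df <- dipole_potential(inp$traj, p$n_bins)
        emit("potential", df, list(n_bins = p$n_bins))
        df
      },
      rdf = function() {
        rmax <- if (is.na(p$rdf_rmax)) min(inp$traj$boxes) / 2
                else p$rdf_rmax
        df <- radial_distribution(inp$traj, p$rdf_selA, p$rdf_selB,
                                  rmax, p$rdf_dr)
        emit("rdf", df, list(selA = p$rdf_selA, selB = p$rdf_selB,
                             r_max_nm = rmax, dr_nm = p$rdf_dr))
        df
      },
      contacts = function() {
        m <- contact_recurrence(inp$traj, p$guest_groups, p$lipid_classes,
                                p$contact_cutoff)
        fn <- "contacts.tsv"
        write_recurrence_tsv(m, file.path(config$outdir, fn))
        files <<- c(files, fn)
        m
      },
      msd = function() {
        df <- lateral_msd(inp$traj, p$msd_sel, assignment)
        emit("msd", df, list(sel = p$msd_sel))
        fit <- fit_diffusion(df, p$msd_window)
        emit("diffusion", data.frame(D_nm2_per_ps = fit$D_nm2_per_ps,
                                     slope = fit$slope,
                                     n_points = fit$n_points),
             list(window = paste(p$msd_window, collapse = "-")))
        list(msd = df, fit = fit)
      },
      flipflops = function() {
        ev <- detect_flipflops(assignment, p$min_residency_ps)
        emit("flipflops", ev, list(min_residency_ps = p$min_residency_ps))
        ev
      }))
  }
  manifest <- list(
    package = "bilayr",
    version = as.character(packageVersion("bilayr")),
    seed = config$seed,
    input = if (is.null(config$synthetic)) config$input else
      list(synthetic = config$synthetic),
    analyses = as.list(config$analyses),
    params = serialize_params(config$params),
    files = as.list(files),
    status = status,
    overall_status = if (all(unlist(status) == "ok")) "ok" else "failed")
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (manifest$overall_status != "ok")
    warning("one or more analyses failed; see manifest status")
  invisible(manifest)
}

serialize_params <- function(p) {
  lapply(p, function(v) if (is.list(v)) lapply(v, as.character) else v)
}

#' Compare two analysis bundles observable by observable
#'
#' Reads the manifests of two result directories (e.g. a bilayer with
#' and without a guest amphiphile), refuses the comparison if the
#' shared analyses were run with different parameters (printing the
#' differing parameter names), and produces per-observable paired
#' tables (A, B, delta = B - A) for thickness, area per lipid, per-bond
#' P2, per-carbon S_CD, the dipole-potential extremum, and the fitted
#' diffusion coefficient.
#'
#' @param dirA,dirB result directories written by [run_pipeline()].
#' @return named list of delta data.frames (only observables present in
#'   both bundles).
#' @export
compare_conditions <- function(dirA, dirB) {
  mA <- jsonlite::read_json(file.path(dirA, "manifest.json"),
                            simplifyVector = TRUE)
  mB <- jsonlite::read_json(file.path(dirB, "manifest.json"),
                            simplifyVector = TRUE)
  shared <- intersect(unlist(mA$analyses), unlist(mB$analyses))
  if (!length(shared))
    stop("the two bundles share no analyses; nothing to compare")
  diffp <- names(which(vapply(names(mA$params), function(k)
    !identical(mA$params[[k]], mB$params[[k]]), logical(1))))
  if (length(diffp))
    stop("bundles were run with different parameters: ",
         paste(diffp, collapse = ", "),
         "; refusing a confounded comparison")
  read_tsv <- function(dir, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) return(NULL)
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  out <- list()
  scalar_mean <- function(name, col) {
    a <- read_tsv(dirA, name); b <- read_tsv(dirB, name)
    if (is.null(a) || is.null(b)) return(NULL)
    va <- mean(a[[col]], na.rm = TRUE)
    vb <- mean(b[[col]], na.rm = TRUE)
    data.frame(observable = name, A = va, B = vb, delta = vb - va)
  }
  if ("thickness" %in% shared)
    out$thickness <- scalar_mean("thickness", "thickness_nm")
  if ("apl" %in% shared)
    out$apl <- scalar_mean("apl", "apl_nm2")
  if ("p2" %in% shared) {
    a <- read_tsv(dirA, "p2"); b <- read_tsv(dirB, "p2")
    m <- merge(a[, c("label", "p2")], b[, c("label", "p2")], by = "label",
               suffixes = c("_A", "_B"))
    m$delta <- m$p2_B - m$p2_A
    out$p2 <- m
  }
  if ("scd" %in% shared) {
    a <- read_tsv(dirA, "scd"); b <- read_tsv(dirB, "scd")
    m <- merge(a[, c("carbon_index", "scd")], b[, c("carbon_index", "scd")],
               by = "carbon_index", suffixes = c("_A", "_B"))
    m$delta <- m$scd_B - m$scd_A
    out$scd <- m
  }
  if ("potential" %in% shared) {
    a <- read_tsv(dirA, "potential"); b <- read_tsv(dirB, "potential")
    ea <- a$psi_V[which.max(abs(a$psi_V))]
    eb <- b$psi_V[which.max(abs(b$psi_V))]
    out$potential_extremum <- data.frame(observable = "potential_extremum",
                                         A = ea, B = eb, delta = eb - ea)
  }
  if ("msd" %in% shared) {
    a <- read_tsv(dirA, "diffusion"); b <- read_tsv(dirB, "diffusion")
    if (!is.null(a) && !is.null(b))
      out$diffusion <- data.frame(observable = "D_nm2_per_ps",
                                  A = a$D_nm2_per_ps, B = b$D_nm2_per_ps,
                                  delta = b$D_nm2_per_ps - a$D_nm2_per_ps)
  }
  out
}
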