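#' Sampling ranges for random network architectures
#'
#' Each of the five architecture fields gets a `(low, high)` range sampled
#' log-uniformly (counts are rounded). Defaults span a factor of 8 around
#' the reference counts and a factor of 4 around the reference polymer pool,
#' realizing networks from sparse to dense.
#'
#' @param n_nucleators,n_arp23,n_motors,n_crosslinkers,polymer_pool numeric
#'   length-2 `(low, high)` ranges.
#' @param domain_radius domain radius shared by all sampled architectures
#'   (um).
#' @return an object of class `"sampling_ranges"`.
#' @export
sampling_ranges <- function(n_nucleators = c(57, 452),
                            n_arp23 = c(57, 452),
                            n_motors = c(339, 2715),
                            n_crosslinkers = c(679, 5431),
                            polymer_pool = c(240, 960),
                            domain_radius = 6) {
  rr <- list(n_nucleators = n_nucleators, n_arp23 = n_arp23,
             n_motors = n_motors, n_crosslinkers = n_crosslinkers,
             polymer_pool = polymer_pool)
  for (nm in names(rr)) {
    r <- rr[[nm]]
    if (length(r) != 2 || r[1] <= 0 || r[1] > r[2])
      stop(sprintf("invalid range for %s: need 0 < low <= high", nm),
           call. = FALSE)
  }
  structure(c(rr, list(domain_radius = domain_radius)),
            class = "sampling_ranges")
}

#' Desk-scale sampling ranges
#'
#' Area-scaled version of [sampling_ranges()]: counts and polymer pool are
#' multiplied by `(domain_radius / 6)^2` so the sampled polymer-density
#' spectrum (sparse to dense) is preserved while the networks stay small
#' enough for fast paired sweeps.
#'
#' @param domain_radius reduced domain radius (um); default 2.5.
#' @return a [sampling_ranges()].
#' @export
sampling_ranges_desk <- function(domain_radius = 2.5) {
  s <- (domain_radius / 6)^2
  r <- sampling_ranges()
  sampling_ranges(n_nucleators = pmax(1, round(r$n_nucleators * s)),
                  n_arp23 = pmax(1, round(r$n_arp23 * s)),
                  n_motors = pmax(1, round(r$n_motors * s)),
                  n_crosslinkers = pmax(1, round(r$n_crosslinkers * s)),
                  polymer_pool = r$polymer_pool * s,
                  domain_radius = domain_radius)
}

#' Reference network architecture
#'
#' The fixed architecture used as the package's reference condition: a dense,
#' well-percolated network. The full scale uses the 6 um domain; the desk
#' scale is the quarter-area reduction (3 um domain) with the same polymer
#' density, used by fast calibration runs and the scaled-down sweeps.
#'
#' @param scale `"full"` or `"desk"`.
#' @param architecture_seed,dynamics_seed seeds.
#' @param ... overrides passed to [architecture_params()].
#' @return an [architecture_params()].
#' @export
reference_architecture <- function(scale = c("full", "desk"),
                                   architecture_seed = 1L,
                                   dynamics_seed = 2L, ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    full = list(n_nucleators = 160, n_arp23 = 160, n_motors = 960,
                n_crosslinkers = 1920, polymer_pool = 480, domain_radius = 6),
    desk = list(n_nucleators = 40, n_arp23 = 40, n_motors = 240,
                n_crosslinkers = 480, polymer_pool = 120, domain_radius = 3))
  args <- utils::modifyList(c(base, list(architecture_seed = architecture_seed,
                                         dynamics_seed = dynamics_seed)),
                            list(...))
  do.call(architecture_params, args)
}

# deterministic 31-bit sub-seed from (master_seed, index, stream)
derive_seed <- function(master_seed, index, stream = 0) {
  x <- (as.double(master_seed) %% 2147483647) * 48271 +
    as.double(index) * 16807 + as.double(stream) * 69621 + 1
  as.integer(x %% 2147483629 + 1)
}

#' Sample one random network architecture
#'
#' Deterministic function of `(master_seed, index)`: the five fields are
#' drawn log-uniformly from their ranges (counts rounded), and the
#' architecture and dynamics seeds are derived from the same pair so every
#' architecture is exactly re-creatable.
#'
#' @param ranges a [sampling_ranges()].
#' @param index architecture index (1-based).
#' @param master_seed master seed of the sweep.
#' @param ... protocol overrides passed to [architecture_params()].
#' @return an [architecture_params()].
#' @export
sample_architecture <- function(ranges, index, master_seed, ...) {
  draw <- with_seed(derive_seed(master_seed, index, 0), {
    vapply(c("n_nucleators", "n_arp23", "n_motors", "n_crosslinkers",
             "polymer_pool"),
           function(nm) {
             r <- ranges[[nm]]
             exp(stats::runif(1, log(r[1]), log(r[2])))
           }, 0)
  })
  args <- list(n_nucleators = round(draw[["n_nucleators"]]),
               n_arp23 = round(draw[["n_arp23"]]),
               n_motors = round(draw[["n_motors"]]),
               n_crosslinkers = round(draw[["n_crosslinkers"]]),
               polymer_pool = draw[["polymer_pool"]],
               domain_radius = ranges$domain_radius,
               architecture_seed = derive_seed(master_seed, index, 1),
               dynamics_seed = derive_seed(master_seed, index, 2))
  do.call(architecture_params, utils::modifyList(args, list(...)))
}

#' Named perturbations of an architecture
#'
#' Presets fix the factors used by the paired comparisons: doubling myosin
#' (`myosin_x2`), doubling F-actin (`actin_x2`, polymer pool doubled at
#' fixed filament number, i.e. longer filaments), both (`myosin_actin_x2`),
#' a 33% Arp2/3 increase (`arp_x1.33`, factor 4/3 rounded half-up), all
#' three (`all_three`), and a 30% polymer-mass reduction (`polymer_x0.7`,
#' shorter filaments). `custom` takes explicit multipliers.
#'
#' @param name preset name.
#' @param multipliers named numeric multipliers for `custom` (over
#'   `n_nucleators`, `n_arp23`, `n_motors`, `n_crosslinkers`,
#'   `polymer_pool`).
#' @return an object of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(name = c("identity", "myosin_x2", "actin_x2",
                                       "myosin_actin_x2", "arp_x1.33",
                                       "all_three", "polymer_x0.7", "custom"),
                              multipliers = NULL) {
  name <- match.arg(name)
  base <- c(n_nucleators = 1, n_arp23 = 1, n_motors = 1,
            n_crosslinkers = 1, polymer_pool = 1)
  m <- switch(name,
    identity = base,
    myosin_x2 = replace(base, "n_motors", 2),
    actin_x2 = replace(base, "polymer_pool", 2),
    myosin_actin_x2 = replace(base, c("n_motors", "polymer_pool"), 2),
    `arp_x1.33` = replace(base, "n_arp23", 4 / 3),
    all_three = replace(base, c("n_motors", "polymer_pool", "n_arp23"),
                        c(2, 2, 4 / 3)),
    `polymer_x0.7` = replace(base, "polymer_pool", 0.7),
    custom = {
      if (is.null(multipliers)) stop("custom perturbation needs multipliers",
                                     call. = FALSE)
      mm <- base
      if (!all(names(multipliers) %in% names(base)))
        stop("unknown multiplier field(s): ",
             paste(setdiff(names(multipliers), names(base)), collapse = ", "),
             call. = FALSE)
      mm[names(multipliers)] <- multipliers
      mm
    })
  if (any(m <= 0)) stop("multipliers must be strictly positive", call. = FALSE)
  structure(list(name = name, multipliers = m), class = "perturbation_spec")
}

# round-half-up for perturbed counts (e.g. 300 * 4/3 -> 400)
round_half_up <- function(x) floor(x + 0.5)

#' Apply a perturbation to an architecture
#'
#' Counts are multiplied and rounded half-up; the polymer pool is scaled
#' continuously. Seeds and protocol are unchanged, so the perturbed
#' simulation replays the same stochastic history on the altered
#' composition (matched-pair design).
#'
#' @param arch an [architecture_params()].
#' @param spec a [perturbation_spec()] (or preset name).
#' @return the perturbed [architecture_params()].
#' @export
apply_perturbation <- function(arch, spec) {
  if (is.character(spec)) spec <- perturbation_spec(spec)
  m <- spec$multipliers
  out <- arch
  out$n_nucleators <- as.integer(round_half_up(arch$n_nucleators * m["n_nucleators"]))
  out$n_arp23 <- as.integer(round_half_up(arch$n_arp23 * m["n_arp23"]))
  out$n_motors <- as.integer(round_half_up(arch$n_motors * m["n_motors"]))
  out$n_crosslinkers <- as.integer(round_half_up(arch$n_crosslinkers *
                                                   m["n_crosslinkers"]))
  out$polymer_pool <- arch$polymer_pool * m[["polymer_pool"]]
  out
}

# polymer length per unit domain area (um / um^2)
density_metric <- function(arch) {
  arch$polymer_pool / (pi * arch$domain_radius^2)
}

# fields that determine phase 1: when unchanged by a perturbation, the frozen
# assembly can be replayed instead of recomputed
assembly_signature <- function(arch) {
  paste(arch$n_nucleators, arch$n_arp23, arch$polymer_pool,
        arch$domain_radius, arch$growth_speed, arch$assembly_duration,
        arch$architecture_seed)
}

#' Run one matched reference/perturbed pair
#'
#' Runs the full pipeline (assembly, injection, contraction, fit) for the
#' reference architecture and its perturbed copy with matched seeds, and
#' returns one sweep row. A failed fit marks the row `failed` rather than
#' dropping it.
#'
#' @param arch an [architecture_params()].
#' @param spec a [perturbation_spec()] or preset name.
#' @param mech,binders simulation parameters.
#' @param architecture_id identifier recorded in the row.
#' @param reference optionally, the precomputed result of
#'   [contract_architecture()] for `arch` (reused across specs by
#'   [run_sweep()]).
#' @param matched_seeds replay the reference's stochastic history on the
#'   perturbed composition (default, variance-reducing); `FALSE` redraws the
#'   perturbed run's dynamics seed for robustness checks.
#' @return a one-row data frame: `architecture_id`, `spec`,
#'   `density_metric`, `B_reference`, `B_perturbed`, `uniform_reference`,
#'   `uniform_perturbed`, `failed`.
#' @export
run_pair <- function(arch, spec, mech = mechanics_params(),
                     binders = binder_param_set(), architecture_id = 1L,
                     reference = NULL, matched_seeds = TRUE,
                     reference_frozen = NULL) {
  if (is.character(spec)) spec <- perturbation_spec(spec)
  ref <- if (is.null(reference)) {
    tryCatch(contract_architecture(arch, mech, binders),
             error = function(e) NULL)
  } else reference
  parch <- apply_perturbation(arch, spec)
  if (!matched_seeds) {
    parch$dynamics_seed <- derive_seed(arch$dynamics_seed, 1, 3)
  }
  reuse <- if (!is.null(reference_frozen) &&
               identical(assembly_signature(parch), assembly_signature(arch)))
    reference_frozen else NULL
  pert <- tryCatch(
    contract_architecture(parch, mech, binders, frozen = reuse),
    error = function(e) NULL)
  failed <- is.null(ref) || is.null(pert) ||
    !ref$fit$converged || !pert$fit$converged
  data.frame(
    architecture_id = architecture_id,
    spec = spec$name,
    density_metric = density_metric(arch),
    B_reference = if (is.null(ref)) NA_real_ else ref$fit$B,
    B_perturbed = if (is.null(pert)) NA_real_ else pert$fit$B,
    uniform_reference = if (is.null(ref)) NA else
      ref$connectivity$uniform_contraction,
    uniform_perturbed = if (is.null(pert)) NA else
      pert$connectivity$uniform_contraction,
    failed = failed)
}

#' Run the random-architecture perturbation sweep
#'
#' Samples `n_architectures` architectures from `ranges`, runs each
#' reference once and each perturbation against it with matched seeds, and
#' returns the scatter table (one row per architecture per perturbation).
#' With an `outdir`, one CSV per spec (`sweep_<spec>.csv`) plus
#' `summary.csv` are written and completed rows are skipped on re-runs
#' (resumability); individual failures are recorded, not fatal. The output
#' is a pure function of `(master_seed, ranges, specs, n_architectures)`.
#'
#' @param n_architectures number of random architectures.
#' @param specs character vector of preset names (or list of
#'   [perturbation_spec()]).
#' @param ranges a [sampling_ranges()].
#' @param master_seed master seed.
#' @param mech,binders simulation parameters.
#' @param outdir optional output directory for CSVs.
#' @param progress print one line per architecture.
#' @param ... protocol overrides forwarded to [sample_architecture()].
#' @return data frame of sweep rows (class `"sweep_table"`).
#' @export
run_sweep <- function(n_architectures, specs, ranges = sampling_ranges(),
                      master_seed = 1L, mech = mechanics_params(),
                      binders = binder_param_set(), outdir = NULL,
                      progress = FALSE, ...) {
  stopifnot(n_architectures >= 1)
  specs <- lapply(specs, function(s)
    if (is.character(s)) perturbation_spec(s) else s)
  spec_names <- vapply(specs, `[[`, "", "name")
  done <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(outdir, sprintf("sweep_%s.csv", spec_names))
    old <- lapply(files[file.exists(files)], utils::read.csv)
    if (length(old)) done <- do.call(rbind, old)
  }
  rows <- list()
  for (i in seq_len(n_architectures)) {
    arch <- sample_architecture(ranges, i, master_seed, ...)
    todo <- spec_names
    if (!is.null(done)) {
      have <- done$spec[done$architecture_id == i & !done$failed]
      todo <- setdiff(todo, have)
    }
    if (length(todo) == 0) next
    frozen <- tryCatch(assemble_network(arch, mech, binders),
                       error = function(e) NULL)
    ref <- if (is.null(frozen)) NULL else
      tryCatch(contract_architecture(arch, mech, binders, frozen = frozen),
               error = function(e) NULL)
    for (sn in todo) {
      sp <- specs[[match(sn, spec_names)]]
      rows[[length(rows) + 1]] <-
        run_pair(arch, sp, mech, binders, architecture_id = i,
                 reference = ref, reference_frozen = frozen)
    }
    if (progress)
      message(sprintf("architecture %d/%d done (%d fibers seeded)",
                      i, n_architectures, arch$n_nucleators))
  }
  tab <- do.call(rbind, rows)
  if (!is.null(done)) tab <- rbind(done, tab)
  if (!is.null(tab)) {
    tab <- tab[order(tab$spec, tab$architecture_id), ]
    rownames(tab) <- NULL
  }
  class(tab) <- c("sweep_table", "data.frame")
  if (!is.null(outdir)) {
    for (sn in unique(tab$spec)) {
      utils::write.csv(tab[tab$spec == sn, , drop = FALSE],
                       file.path(outdir, sprintf("sweep_%s.csv", sn)),
                       row.names = FALSE)
    }
    utils::write.csv(summarize_sweep(tab), file.path(outdir, "summary.csv"),
                     row.names = FALSE)
  }
  tab
}

#' Summarize a perturbation sweep
#'
#' Per perturbation: fraction of architectures whose contraction rate
#' increased, median relative change `(B_perturbed - B_reference) /
#' B_reference`, the same stratified by polymer-density quartile, and the
#' count of percolation failures (`uniform_perturbed == FALSE`).
#'
#' @param table a sweep table from [run_sweep()].
#' @return data frame with one row per (spec, stratum); stratum `"all"`
#'   plus `"q1"`..`"q4"` (density quartiles, q1 sparsest).
#' @export
summarize_sweep <- function(table) {
  tab <- table[!table$failed & !is.na(table$B_reference), , drop = FALSE]
  if (nrow(tab) == 0) stop("no successful sweep rows to summarize",
                           call. = FALSE)
  qs <- stats::quantile(unique(tab[, c("architecture_id", "density_metric")])$density_metric,
                        c(0.25, 0.5, 0.75))
  stratum_of <- function(d) {
    ifelse(d <= qs[1], "q1", ifelse(d <= qs[2], "q2",
                                    ifelse(d <= qs[3], "q3", "q4")))
  }
  tab$stratum <- stratum_of(tab$density_metric)
  one <- function(rows, spec, stratum) {
    rel <- (rows$B_perturbed - rows$B_reference) / rows$B_reference
    data.frame(spec = spec, stratum = stratum, n = nrow(rows),
               fraction_increased = mean(rows$B_perturbed > rows$B_reference),
               median_rel_change = stats::median(rel),
               n_percolation_failures = sum(!rows$uniform_perturbed,
                                            na.rm = TRUE))
  }
  out <- list()
  for (sn in unique(tab$spec)) {
    st <- tab[tab$spec == sn, , drop = FALSE]
    out[[length(out) + 1]] <- one(st, sn, "all")
    for (q in c("q1", "q2", "q3", "q4")) {
      sq <- st[st$stratum == q, , drop = FALSE]
      if (nrow(sq) > 0) out[[length(out) + 1]] <- one(sq, sn, q)
    }
  }
  do.call(rbind, out)
}
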