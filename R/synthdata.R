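#' Configuration for the synthetic compound-data generator
#'
#' The generator emulates the statistical structure a multi-task
#' pharmacokinetic model assumes: positive, right-skewed human clearance
#' (CL, mL/min/kg) and steady-state volume of distribution (VDss, L/kg)
#' whose log10 values share a latent correlation; allometrically correlated
#' animal PK values for rat, dog and monkey; plasma fraction-unbound and
#' pKa covariates carrying signal; and a fraction of compounds missing one
#' of the two human targets.
#'
#' The two task latents are
#' \deqn{t_{CL} = \sqrt{\rho}\, s + \sqrt{1-\rho}\, z_1 + \delta z_{mol}}
#' \deqn{t_{VD} = \sqrt{\rho}\, s + \sqrt{1-\rho}\, z_2 + \delta z_{mol}}
#' with \eqn{s, z_1, z_2} independent standard normals, \eqn{z_{mol}} the
#' standardized heavy-atom count and \eqn{\delta} = `mol_signal_weight`;
#' then \eqn{\log_{10} CL = \mu_{CL} + \sigma_{CL} t_{CL}} and likewise for
#' VDss.  With \eqn{\delta = 0} the log-scale CL-VD correlation equals
#' `rho_shared` exactly.
#'
#' @param n_compounds number of compounds to generate.
#' @param rho_shared correlation of the two task latents, in \[0, 1\].
#' @param mu_logCL,sigma_logCL mean and sd of log10 human CL (mL/min/kg).
#' @param mu_logVD,sigma_logVD mean and sd of log10 human VDss (L/kg).
#' @param animal_noise_sd sd of species-level log10 noise.
#' @param mol_signal_weight weight of the molecule-size signal in both
#'   task latents.
#' @param missing_frac_cl,missing_frac_vd fractions of compounds masked
#'   missing for each target, in \[0, 1); no compound loses both.
#' @param max_heavy_atoms largest molecule size drawn by the SMILES
#'   generator.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 700L, rho_shared = 0.6,
                         mu_logCL = 0.6, sigma_logCL = 0.45,
                         mu_logVD = -0.15, sigma_logVD = 0.5,
                         animal_noise_sd = 0.3, mol_signal_weight = 0.25,
                         missing_frac_cl = 0.1, missing_frac_vd = 0.1,
                         max_heavy_atoms = 30L, seed = 1L) {
  stopifnot(n_compounds >= 1, rho_shared >= 0, rho_shared <= 1,
            sigma_logCL > 0, sigma_logVD > 0, animal_noise_sd >= 0,
            missing_frac_cl >= 0, missing_frac_cl < 1,
            missing_frac_vd >= 0, missing_frac_vd < 1,
            missing_frac_cl + missing_frac_vd <= 1,
            max_heavy_atoms >= 2)
  structure(list(n_compounds = as.integer(n_compounds),
                 rho_shared = rho_shared,
                 mu_logCL = mu_logCL, sigma_logCL = sigma_logCL,
                 mu_logVD = mu_logVD, sigma_logVD = sigma_logVD,
                 animal_noise_sd = animal_noise_sd,
                 mol_signal_weight = mol_signal_weight,
                 missing_frac_cl = missing_frac_cl,
                 missing_frac_vd = missing_frac_vd,
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Element vocabulary with maximum valence; all bonds emitted are single.
.elem_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L)
.elem_weights <- c(C = 0.62, N = 0.12, O = 0.12, S = 0.04, F = 0.05, Cl = 0.05)

#' Generate random valid SMILES strings
#'
#' Molecules are assembled as random trees of singly bonded heavy atoms
#' drawn from \{C, N, O, S, F, Cl\} with valence respected by construction,
#' plus optional all-carbon 5/6-membered ring substituents written with
#' their own ring-closure digits.  Every emitted string is syntactically
#' valid SMILES; duplicates are permitted.
#'
#' @param n number of SMILES to generate (>= 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @param max_heavy_atoms upper bound on heavy atoms per molecule (>= 2).
#' @return character vector of length `n`.
#' @export
generate_molecules <- function(n, seed, max_heavy_atoms = 30L) {
  stopifnot(n >= 1, max_heavy_atoms >= 2)
  with_seed(seed, vapply(seq_len(n), function(i)
    .one_molecule(max_heavy_atoms), character(1)))
}

.one_molecule <- function(max_heavy) {
  target <- sample(seq(min(4L, max_heavy), max_heavy), 1L)
  # node fields: element, remaining valence, children (indices), ring size
  elems <- character(0); remain <- integer(0)
  children <- list(); ringsz <- integer(0)
  add_node <- function(el, used, ring = 0L) {
    elems[[length(elems) + 1L]] <<- el
    remain[[length(remain) + 1L]] <<- .elem_valence[[el]] - used
    children[[length(children) + 1L]] <<- integer(0)
    ringsz[[length(ringsz) + 1L]] <<- ring
    length(elems)
  }
  root_el <- sample(c("C", "N", "O"), 1L, prob = c(0.8, 0.1, 0.1))
  add_node(root_el, 0L)
  n_heavy <- 1L
  while (n_heavy < target) {
    open <- which(remain > 0L & ringsz == 0L)
    if (!length(open)) break
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    left <- target - n_heavy
    if (left >= 5L && runif(1) < 0.25) {
      size <- if (left >= 6L && runif(1) < 0.5) 6L else 5L
      id <- add_node("C", 3L, ring = size)   # ring anchor: parent + 2 ring bonds
      children[[parent]] <- c(children[[parent]], id)
      remain[[parent]] <- remain[[parent]] - 1L
      n_heavy <- n_heavy + size
    } else {
      pool <- if (left == 1L || runif(1) < 0.35) .elem_weights else
        .elem_weights[c("C", "N", "O", "S")]
      el <- sample(names(pool), 1L, prob = pool)
      id <- add_node(el, 1L)
      children[[parent]] <- c(children[[parent]], id)
      remain[[parent]] <- remain[[parent]] - 1L
      n_heavy <- n_heavy + 1L
    }
  }
  ring_counter <- 0L
  write_node <- function(i) {
    if (ringsz[[i]] > 0L) {
      ring_counter <<- ring_counter + 1L
      d <- if (ring_counter < 10L) as.character(ring_counter) else
        paste0("%", ring_counter)
      return(paste0("C", d, strrep("C", ringsz[[i]] - 2L), "C", d))
    }
    kids <- children[[i]]
    out <- elems[[i]]
    if (length(kids)) {
      subs <- vapply(kids, write_node, character(1))
      if (length(subs) > 1L)
        out <- paste0(out, paste0("(", subs[-length(subs)], ")",
                                  collapse = ""))
      out <- paste0(out, subs[length(subs)])
    }
    out
  }
  write_node(1L)
}

# Heavy-atom count straight off the SMILES text emitted by the generator
# (single-letter organic subset plus Cl; no aromatic atoms are produced).
.heavy_count <- function(smiles) {
  vapply(smiles, function(s) {
    s <- gsub("Cl", "X", s, fixed = TRUE)
    sum(strsplit(s, "")[[1]] %in% c("C", "N", "O", "S", "F", "X"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Latent generative model for one compound's PK targets
#'
#' Applies the shared-latent equations documented in [synth_config()].
#' All arguments are vectorized.
#'
#' @param s shared standard-normal latent.
#' @param z1,z2 task-specific standard-normal latents.
#' @param z_mol standardized heavy-atom count.
#' @param cfg a [synth_config()].
#' @return list with `t_cl`, `t_vd`, `log_cl`, `log_vd` (log10 scale).
#' @export
latent_pk_model <- function(s, z1, z2, z_mol, cfg) {
  rho <- cfg$rho_shared; delta <- cfg$mol_signal_weight
  t_cl <- sqrt(rho) * s + sqrt(1 - rho) * z1 + delta * z_mol
  t_vd <- sqrt(rho) * s + sqrt(1 - rho) * z2 + delta * z_mol
  list(t_cl = t_cl, t_vd = t_vd,
       log_cl = cfg$mu_logCL + cfg$sigma_logCL * t_cl,
       log_vd = cfg$mu_logVD + cfg$sigma_logVD * t_vd)
}

# Species-level allometric intercept/slope on the log10 scale, relative to
# the human latent of the matching task.
default_species_params <- function(cfg) {
  list(
    cl = list(rat    = c(alpha = cfg$mu_logCL + 0.85, kappa = 0.90 * cfg$sigma_logCL),
              dog    = c(alpha = cfg$mu_logCL + 0.35, kappa = 0.85 * cfg$sigma_logCL),
              monkey = c(alpha = cfg$mu_logCL + 0.55, kappa = 0.90 * cfg$sigma_logCL)),
    vd = list(rat    = c(alpha = cfg$mu_logVD + 0.15, kappa = 0.90 * cfg$sigma_logVD),
              dog    = c(alpha = cfg$mu_logVD + 0.10, kappa = 0.85 * cfg$sigma_logVD),
              monkey = c(alpha = cfg$mu_logVD + 0.05, kappa = 0.90 * cfg$sigma_logVD)))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Generate a synthetic multi-species PK dataset
#'
#' Draws molecules, latents and covariates under `cfg` and returns a
#' compound table in the canonical column layout together with the latent
#' truth retained for diagnostics.  Animal values are generated as
#' `alpha_species + kappa_species * t_task + Normal(0, animal_noise_sd)` on
#' the log10 scale; fraction unbound per species is a logistic transform of
#' the VD latent plus noise, strictly inside (0, 1); pKa values come from
#' truncated normals.  Target masking never removes both endpoints from
#' the same compound.
#'
#' @param cfg a [synth_config()].
#' @param species_params optional override of the allometric parameters, in
#'   the shape returned by `default_species_params(cfg)`.
#' @return object of class `pk_dataset`: list with `records` (data.frame,
#'   one row per compound) and `truth` (data.frame of latents; diagnostics
#'   only — never fed to model fitting).
#' @export
generate_pk_dataset <- function(cfg, species_params = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  sp <- species_params %||% default_species_params(cfg)
  n <- cfg$n_compounds
  smiles <- generate_molecules(n, cfg$seed, cfg$max_heavy_atoms)
  heavy <- .heavy_count(smiles)
  with_seed(cfg$seed + 500000L, {
    z_mol <- if (sd(heavy) > 0) (heavy - mean(heavy)) / sd(heavy) else heavy * 0
    s <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
    lat <- latent_pk_model(s, z1, z2, z_mol, cfg)
    rec <- data.frame(
      name = sprintf("CPD_%05d", seq_len(n)),
      smiles = smiles,
      human_CL_mL_min_kg = 10^lat$log_cl,
      human_VDss_L_kg = 10^lat$log_vd,
      stringsAsFactors = FALSE)
    for (spec in c("rat", "dog", "monkey")) {
      pcl <- sp$cl[[spec]]; pvd <- sp$vd[[spec]]
      rec[[paste0(spec, "_CL_mL_min_kg")]] <-
        10^(pcl[["alpha"]] + pcl[["kappa"]] * lat$t_cl +
              rnorm(n, 0, cfg$animal_noise_sd))
      rec[[paste0(spec, "_VDss_L_kg")]] <-
        10^(pvd[["alpha"]] + pvd[["kappa"]] * lat$t_vd +
              rnorm(n, 0, cfg$animal_noise_sd))
    }
    fup_shift <- c(human = 0, rat = 0.3, dog = 0.15, monkey = 0.1)
    for (spec in c("human", "rat", "dog", "monkey")) {
      rec[[paste0(spec, "_fup")]] <-
        plogis(-0.8 + fup_shift[[spec]] - 0.9 * lat$t_vd + rnorm(n, 0, 0.5))
    }
    rec$pKa_Acid <- .rtruncnorm(n, 5, 2, 1, 13)
    rec$pKa_base <- .rtruncnorm(n, 8, 2, 1, 13)
    u <- runif(n)
    rec$human_CL_mL_min_kg[u < cfg$missing_frac_cl] <- NA_real_
    rec$human_VDss_L_kg[u > 1 - cfg$missing_frac_vd] <- NA_real_
    structure(list(records = rec,
                   truth = data.frame(s = s, t_cl = lat$t_cl,
                                      t_vd = lat$t_vd, heavy = heavy),
                   config = cfg),
              class = "pk_dataset")
  })
}

#' Write a synthetic dataset as CSV
#'
#' One row per compound; missing targets become empty cells.
#'
#' @param dataset a `pk_dataset` or a plain compound data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(dataset, path) {
  rec <- if (inherits(dataset, "pk_dataset")) dataset$records else dataset
  write.csv(rec, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("<pk_dataset> %d compounds (seed %d, rho_shared %.2f)\n",
              nrow(x$records), x$config$seed, x$config$rho_shared))
  invisible(x)
}
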