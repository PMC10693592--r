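#' Generator configuration for synthetic screens
#'
#' Defines the data-generating model that emulates the statistical structure
#' of a randomized SynCom protection screen: a 35-strain pool, five-strain
#' communities, 136 training communities split over two experiments, a
#' 70-community test experiment, four plants per box, additive strain effects
#' with pairwise synergies, a commensal-colonization coupling with
#' per-community random slope, an evenness coupling with per-community random
#' slope, box and experiment random effects, detection floors and ambiguous
#' strain pairs.
#'
#' Per plant, on the log10 scale:
#' `pathogen = axenic_mean + experiment + sum(delta_s) + sum(gamma_pairs) +
#'  (beta_c + b_box) * (C - commensal_mean) + (eta + h_box) * (J - E[J]) +
#'  u_box + eps`, where `C ~ N(commensal_mean, commensal_sd)` is the plant's
#' total commensal colonization, strain shares are Dirichlet and `J` is the
#' Pielou evenness of the shares, centered at its analytic expectation for
#' the community size (~0.5 for five members at the default concentration).
#'
#' Three strong pathogen-reducing strains (delta = -2 each, additive in
#' combination), one intermediate strain (-1), and one weak partner (-0.3)
#' whose pairing with the intermediate strain carries a -1 synergy are
#' implanted; all other strains are neutral.
#'
#' @param ... Overrides for any default field (see the returned list).
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(...) {
  pool <- default_pool(35)
  delta <- setNames(numeric(35), pool$strain_ids)
  delta[c("strain_01", "strain_02", "strain_03")] <- -2.0 # PR strains
  delta["strain_04"] <- -1.0                              # intermediate
  delta["strain_05"] <- -0.3                              # weak partner
  cfg <- list(
    pool_size = 35L,
    community_size = 5L,
    n_train_communities = 136L,
    n_train_experiments = 2L,
    n_test_communities = 70L,  # 68 random + SynCom-Low/High control compositions
    plants_per_box = 4L,
    axenic_mean = 8.5,
    experiment_sd = 0.2,
    box_sd = 0.15,
    residual_sd = 0.8,
    strain_effects = delta,
    synergy_effects = tibble::tibble(strain_a = "strain_04",
                                     strain_b = "strain_05",
                                     gamma = -1.0),
    # strain effects are amplified when effect strains are accompanied by
    # other commensals (community context), and the total expected reduction
    # saturates softly near the pathogen establishment floor
    context_amplification = 0.38,
    effect_floor = -4.2,     # log10 reduction at which protection saturates
    effect_softness = 0.3,
    commensal_slope = 1.4,
    commensal_slope_sd = 0.6,
    commensal_mean = 8.0,
    commensal_sd = 0.5,
    evenness_effect = -1.3,
    evenness_effect_sd = 2.2,
    evenness_center = NULL,  # default: analytic E[J | k, alpha], ~0.5 at k=5
    dirichlet_alpha = 0.25,
    detection_floor = 3.5,   # log10 CFU/g; per-strain values only
    # morphologically indistinguishable strain pairs: when both members are
    # inoculated together their counts are pooled (prob. ambiguity_rate per
    # plant), so ambiguity clusters by community as it does on real plates
    ambiguous_pairs = tibble::tibble(
      strain_a = sprintf("strain_%02d", seq(6, 20, by = 2)),
      strain_b = sprintf("strain_%02d", seq(7, 21, by = 2))),
    ambiguity_rate = 0.95,
    n_axenic_boxes = 7L,
    n_axenic_ni_boxes = 2L,
    fresh_weight_mean = 40,
    fresh_weight_sd = 10,
    include_controls = TRUE,
    tree = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown generator fields: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  sds <- c(cfg$experiment_sd, cfg$box_sd, cfg$residual_sd,
           cfg$commensal_slope_sd, cfg$commensal_sd, cfg$evenness_effect_sd,
           cfg$fresh_weight_sd)
  problems <- character()
  if (any(sds < 0)) problems <- c(problems, "standard deviations must be >= 0")
  if (cfg$ambiguity_rate < 0 || cfg$ambiguity_rate > 1) {
    problems <- c(problems, "ambiguity_rate must lie in [0, 1]")
  }
  if (cfg$dirichlet_alpha <= 0) problems <- c(problems, "dirichlet_alpha must be > 0")
  if (cfg$community_size > cfg$pool_size) {
    problems <- c(problems, "community_size cannot exceed pool_size")
  }
  pool_ids <- default_pool(cfg$pool_size)$strain_ids
  if (!all(names(cfg$strain_effects) %in% pool_ids) ||
      length(cfg$strain_effects) != cfg$pool_size) {
    problems <- c(problems, "strain_effects must name every pool strain")
  }
  syn <- cfg$synergy_effects
  if (nrow(syn) && !all(c(syn$strain_a, syn$strain_b) %in% pool_ids)) {
    problems <- c(problems, "synergy strains must be in the pool")
  }
  ap <- cfg$ambiguous_pairs
  if (nrow(ap) && !all(c(ap$strain_a, ap$strain_b) %in% pool_ids)) {
    problems <- c(problems, "ambiguous-pair strains must be in the pool")
  }
  if (length(problems)) stop(paste(problems, collapse = "; "), call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Strains designated as strong pathogen reducers in a config
#' @param config A `generator_config`.
#' @export
pr_strains <- function(config) {
  names(config$strain_effects)[config$strain_effects <= -2]
}

#' Simulate an unrooted strain phylogeny
#'
#' Random binary topology over the pool with positive branch lengths; stands
#' in for a genome-derived tree when only tree *consumption* is of interest.
#'
#' @param pool A [strain_pool()].
#' @param seed Integer seed.
#' @return An unrooted `ape::phylo` with the pool strains as tips.
#' @export
simulate_tree <- function(pool, seed) {
  stopifnot(inherits(pool, "strain_pool"), pool$size >= 3)
  withr_seed(seed, {
    tr <- ape::rtree(pool$size, rooted = FALSE,
                     tip.label = sample(pool$strain_ids))
    tr$edge.length <- tr$edge.length + 0.05 # keep all branches positive
    tr
  })
}

# Designated control compositions: SynCom-Low carries two strong reducers,
# SynCom-High only neutral strains.
control_compositions <- function(config) {
  ids <- names(config$strain_effects)
  pr <- pr_strains(config)
  neutral <- ids[config$strain_effects == 0]
  k <- config$community_size
  list(
    "SynCom-Low" = sort(c(pr[1:2], head(neutral, k - 2))),
    "SynCom-High" = sort(tail(neutral, k)))
}

# Linear predictor pieces shared by screen and validation generation.
# The raw additive effect (delta + gamma) is amplified when the community
# also contains neutral members (context amplification), then passed through
# a soft floor so expected protection saturates near the establishment floor.
community_fixed_effect <- function(members, config) {
  delta <- sum(config$strain_effects[members])
  gamma <- 0
  syn <- config$synergy_effects
  if (nrow(syn)) {
    hit <- syn$strain_a %in% members & syn$strain_b %in% members
    gamma <- sum(syn$gamma[hit])
  }
  raw <- delta + gamma
  has_neutral_co <- any(config$strain_effects[members] == 0) &&
    any(config$strain_effects[members] != 0)
  amplified <- raw * (1 + if (has_neutral_co) config$context_amplification else 0)
  c(delta = delta, gamma = gamma, total = soft_floor(
    amplified, config$effect_floor, config$effect_softness))
}

# Expected Pielou evenness of Dirichlet(alpha) shares over k strains:
# E[H'] = digamma(k a + 1) - digamma(a + 1), so the evenness coupling is
# mean-zero for every community size unless an explicit center is configured.
evenness_center_for <- function(config, k) {
  if (!is.null(config$evenness_center)) return(config$evenness_center)
  if (k < 2) return(0.5)
  a <- config$dirichlet_alpha
  (digamma(k * a + 1) - digamma(a + 1)) / log(k)
}

# Smooth saturation: identity well above `floor`, asymptote at `floor`.
soft_floor <- function(r, floor, softness) {
  if (softness <= 0) return(pmax(r, floor))
  floor + softness * log1p(exp((r - floor) / softness))
}

# Generate all plants of one box. `members = NULL` -> axenic box.
# Returns list(plants, strains, truth_box, truth_plants).
generate_box <- function(box_id, experiment, treatment, community_id, members,
                         exp_effect, config, infected = TRUE) {
  k <- length(members)
  npl <- config$plants_per_box
  u_box <- rnorm(1, 0, config$box_sd)
  b_slope <- rnorm(1, 0, config$commensal_slope_sd)
  h_slope <- rnorm(1, 0, config$evenness_effect_sd)
  fe <- if (k > 0) community_fixed_effect(members, config) else
    c(delta = 0, gamma = 0, total = 0)

  plant_ids <- sprintf("%s_p%d", box_id, seq_len(npl))
  weight <- pmax(5, rnorm(npl, config$fresh_weight_mean, config$fresh_weight_sd))
  eps <- rnorm(npl, 0, config$residual_sd)

  strains_rows <- NULL
  commensal_term <- rep(0, npl)
  evenness_term <- rep(0, npl)
  if (k > 0) {
    C <- rnorm(npl, config$commensal_mean, config$commensal_sd)
    shares <- if (k == 1) matrix(1, npl, 1) else
      t(vapply(seq_len(npl),
               function(i) rdirichlet1(rep(config$dirichlet_alpha, k)),
               numeric(k)))
    j_center <- evenness_center_for(config, k)
    if (k >= 2) {
      J <- apply(shares, 1, function(p) {
        p <- p[p > 0]
        -sum(p * log(p)) / log(k)
      })
    } else {
      J <- rep(j_center, npl) # singleton: evenness undefined, term off
    }
    commensal_term <- (config$commensal_slope + b_slope) * (C - config$commensal_mean)
    evenness_term <- (config$evenness_effect + h_slope) * (J - j_center)

    cfu <- shares * 10^C  # per-strain CFU/g, linear
    floor_lin <- 10^config$detection_floor
    for (i in seq_len(npl)) {
      vals <- cfu[i, ]
      flag <- ifelse(vals < floor_lin, "below_detection", "detected")
      vals[vals < floor_lin] <- floor_lin
      amb_group <- rep(NA_character_, k)
      ap <- config$ambiguous_pairs
      if (nrow(ap)) {
        for (pi in seq_len(nrow(ap))) {
          pair <- match(c(ap$strain_a[pi], ap$strain_b[pi]), members)
          if (anyNA(pair)) next
          if (runif(1) < config$ambiguity_rate) {
            pooled <- sum(vals[pair])
            vals[pair] <- pooled      # pooled count carried on each member row
            flag[pair] <- "ambiguous"
            amb_group[pair] <- sprintf("%s_amb%d", plant_ids[i], pi)
          }
        }
      }
      strains_rows <- rbind(strains_rows, data.frame(
        plant_id = plant_ids[i], strain_id = members, cfu_per_g = vals,
        flag = flag, ambiguity_group = amb_group,
        stringsAsFactors = FALSE))
    }
  } else {
    C <- rep(NA_real_, npl)
    J <- rep(NA_real_, npl)
  }

  y <- if (infected) {
    config$axenic_mean + exp_effect + fe["total"] +
      commensal_term + evenness_term + u_box + eps
  } else rep(NA_real_, npl)

  plants <- tibble::tibble(
    experiment = experiment, box_id = box_id, treatment = treatment,
    community_id = community_id, plant_id = plant_ids,
    fresh_weight_mg = weight,
    pathogen_cfu = if (infected) 10^y else NA_real_,
    excluded = FALSE, exclude_reason = NA_character_)

  truth_box <- tibble::tibble(
    box_id = box_id, experiment = experiment, treatment = treatment,
    community_id = community_id,
    delta_sum = unname(fe["delta"]), gamma_sum = unname(fe["gamma"]),
    fixed_total = unname(fe["total"]),
    u_box = u_box, b_slope = b_slope, h_slope = h_slope,
    exp_effect = exp_effect,
    expected_log10 = config$axenic_mean + exp_effect + unname(fe["total"]))
  truth_plants <- tibble::tibble(
    plant_id = plant_ids, box_id = box_id,
    commensal_log10 = C, evenness_true = J,
    commensal_term = commensal_term, evenness_term = evenness_term,
    residual = eps, pathogen_log10 = if (infected) y else NA_real_)

  list(plants = plants,
       strains = if (is.null(strains_rows)) empty_strains() else
         tibble::as_tibble(strains_rows),
       truth_box = truth_box, truth_plants = truth_plants)
}

empty_strains <- function() {
  tibble::tibble(plant_id = character(), strain_id = character(),
                 cfu_per_g = numeric(), flag = character(),
                 ambiguity_group = character())
}

collect_boxes <- function(box_list, communities, controls) {
  screen_data(
    plants = dplyr::bind_rows(lapply(box_list, `[[`, "plants")),
    strains = dplyr::bind_rows(lapply(box_list, `[[`, "strains")),
    communities = communities,
    controls = controls)
}

#' Generate a full synthetic screen with ground truth
#'
#' Emits a two-experiment training screen (136 random communities, 68 per
#' experiment, plus axenic and SynCom controls), an independent test
#' experiment (68 fresh communities plus the SynCom-Low/High control
#' compositions, none of which occur in training), the simulated strain
#' phylogeny, and a ground-truth record sufficient to reproduce every
#' expected value.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed; all randomness derives from it.
#' @return List with `train` and `test` (`screen_data`, linear scale),
#'   `communities` (combined membership), `tree`, `truth` (list of `boxes`,
#'   `plants`, `config`, `seed`).
#' @export
generate_screen <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- derive_seeds(seed, 4)
  pool <- default_pool(config$pool_size)
  tree <- if (is.null(config$tree)) simulate_tree(pool, seeds[1]) else config$tree

  ctrl_comps <- control_compositions(config)
  n_rand <- config$n_train_communities +
    (config$n_test_communities - if (config$include_controls) 2L else 0L)
  spec <- design_spec(config$community_size, config$pool_size, n_rand)
  cs <- assemble_communities(pool, spec, seeds[2],
                             enforce_unique = TRUE,
                             exclude = unname(ctrl_comps))
  train_comms <- cs$communities[seq_len(config$n_train_communities)]
  test_comms <- cs$communities[-seq_len(config$n_train_communities)]
  names(test_comms) <- sprintf("test_%03d", seq_along(test_comms))
  if (config$include_controls) {
    test_comms <- c(test_comms, list("SynCom-Low" = ctrl_comps$`SynCom-Low`,
                                     "SynCom-High" = ctrl_comps$`SynCom-High`))
  }

  all_comms <- c(train_comms, test_comms,
                 list("SynCom-35" = pool$strain_ids))
  if (config$include_controls) {
    all_comms[["SynCom-Low"]] <- ctrl_comps$`SynCom-Low`
    all_comms[["SynCom-High"]] <- ctrl_comps$`SynCom-High`
  }
  membership <- tibble::tibble(
    community_id = rep(names(all_comms), lengths(all_comms)),
    strain_id = unlist(all_comms, use.names = FALSE))

  controls <- c("axenic", "axenic-NI", "SynCom-35", "SynCom-Low", "SynCom-High")

  per_exp <- split(seq_along(train_comms),
                   rep(seq_len(config$n_train_experiments),
                       length.out = length(train_comms)))

  train_boxes <- list()
  truth_exp <- numeric()
  withr_seed(seeds[3], {
    for (e in seq_len(config$n_train_experiments)) {
      exp_name <- sprintf("exp%d", e)
      exp_eff <- rnorm(1, 0, config$experiment_sd)
      truth_exp[exp_name] <- exp_eff
      bi <- 0L
      add_box <- function(treatment, community_id, members, infected = TRUE) {
        bi <<- bi + 1L
        box_id <- sprintf("%s_box%03d", exp_name, bi)
        train_boxes[[length(train_boxes) + 1L]] <<- generate_box(
          box_id, exp_name, treatment, community_id, members,
          exp_eff, config, infected)
      }
      for (ci in per_exp[[e]]) {
        cid <- names(train_comms)[ci]
        add_box(cid, cid, train_comms[[ci]])
      }
      for (j in seq_len(config$n_axenic_boxes)) add_box("axenic", NA_character_, NULL)
      for (j in seq_len(config$n_axenic_ni_boxes)) {
        add_box("axenic-NI", NA_character_, NULL, infected = FALSE)
      }
      if (config$include_controls) {
        add_box("SynCom-35", "SynCom-35", pool$strain_ids)
        add_box("SynCom-Low", "SynCom-Low", ctrl_comps$`SynCom-Low`)
        add_box("SynCom-High", "SynCom-High", ctrl_comps$`SynCom-High`)
      }
    }
  })

  test_boxes <- list()
  withr_seed(seeds[4], {
    exp_name <- "exp3"
    exp_eff <- rnorm(1, 0, config$experiment_sd)
    truth_exp[exp_name] <- exp_eff
    bi <- 0L
    add_box <- function(treatment, community_id, members, infected = TRUE) {
      bi <<- bi + 1L
      box_id <- sprintf("%s_box%03d", exp_name, bi)
      test_boxes[[length(test_boxes) + 1L]] <<- generate_box(
        box_id, exp_name, treatment, community_id, members,
        exp_eff, config, infected)
    }
    for (cid in names(test_comms)) add_box(cid, cid, test_comms[[cid]])
    for (j in seq_len(config$n_axenic_boxes)) add_box("axenic", NA_character_, NULL)
    for (j in seq_len(config$n_axenic_ni_boxes)) {
      add_box("axenic-NI", NA_character_, NULL, infected = FALSE)
    }
    if (config$include_controls) add_box("SynCom-35", "SynCom-35", pool$strain_ids)
  })

  # test communities evaluated as communities: Low/High are *not* controls there
  test_controls <- c("axenic", "axenic-NI", "SynCom-35")

  truth <- list(
    boxes = dplyr::bind_rows(c(lapply(train_boxes, `[[`, "truth_box"),
                               lapply(test_boxes, `[[`, "truth_box"))),
    plants = dplyr::bind_rows(c(lapply(train_boxes, `[[`, "truth_plants"),
                                lapply(test_boxes, `[[`, "truth_plants"))),
    experiment_effects = truth_exp,
    config = config, seed = as.integer(seed))

  list(train = collect_boxes(train_boxes, membership, controls),
       test = collect_boxes(test_boxes, membership, test_controls),
       communities = membership, tree = tree, truth = truth)
}

#' Generate a synthetic validation experiment
#'
#' Applies the same generative model to arbitrary treatment compositions
#' (single strains, pairs, larger combinations, axenic and SynCom controls),
#' split over two experimental rounds.
#'
#' @param config A [generator_config()].
#' @param treatments Named list of strain-id vectors; `NULL`/empty element =
#'   axenic infected control.
#' @param n_boxes_per_treatment Total boxes per treatment, divided equally
#'   between the two rounds.
#' @param seed Integer seed.
#' @return List with `data` (`screen_data`, linear scale) and `truth`.
#' @export
generate_validation_experiment <- function(config = generator_config(),
                                           treatments,
                                           n_boxes_per_treatment = 6,
                                           seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  pool_ids <- names(config$strain_effects)
  for (tr in treatments) {
    if (length(tr) && !all(tr %in% pool_ids)) {
      stop("unknown strain in treatment definition", call. = FALSE)
    }
  }
  if (is.null(names(treatments)) || any(names(treatments) == "")) {
    stop("treatments must be named", call. = FALSE)
  }
  boxes <- list()
  membership <- tibble::tibble(
    community_id = rep(names(treatments), lengths(treatments)),
    strain_id = unlist(treatments, use.names = FALSE))
  withr_seed(seed, {
    per_round <- ceiling(n_boxes_per_treatment / 2)
    bi <- 0L
    for (r in 1:2) {
      round_name <- sprintf("round%d", r)
      exp_eff <- rnorm(1, 0, config$experiment_sd)
      n_this <- if (r == 1) per_round else n_boxes_per_treatment - per_round
      for (tn in names(treatments)) {
        members <- treatments[[tn]]
        cid <- if (length(members)) tn else NA_character_
        for (j in seq_len(n_this)) {
          bi <- bi + 1L
          box_id <- sprintf("%s_box%03d", round_name, bi)
          boxes[[length(boxes) + 1L]] <- generate_box(
            box_id, round_name, tn, cid,
            if (length(members)) members else NULL, exp_eff, config)
        }
      }
    }
  })
  axenic_like <- names(treatments)[lengths(treatments) == 0]
  data <- collect_boxes(boxes, membership, controls = axenic_like)
  truth <- list(boxes = dplyr::bind_rows(lapply(boxes, `[[`, "truth_box")),
                plants = dplyr::bind_rows(lapply(boxes, `[[`, "truth_plants")),
                config = config, seed = as.integer(seed))
  list(data = data, truth = truth)
}
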