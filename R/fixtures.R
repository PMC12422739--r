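# Fixture generation, run manifests and an in-package enumeration oracle
# for tiny instances (used to stamp expected optima into fixture files).

# Exhaustive optimum for a tiny instance by enumerating case->room-day
# assignments (and, when a surgeon spans two rooms on a day, all execution
# orders). Minutes. Intended for <= ~8 cases over <= ~3 room-days.
brute_force_objective <- function(cases, config, availability = NULL,
                                  formulation = config$formulation,
                                  allocation = NULL) {
  if (is.null(availability))
    availability <- surgeon_availability(rep(list(integer(0)), config$n_surgeons),
                                         config)
  n <- nrow(cases)
  w <- blocks_required(cases$predicted_dos, config$block_minutes)
  g <- cleaning_blocks(config)
  Rb <- regular_blocks(config)
  cap <- day_cap_blocks(config)
  bins <- expand.grid(room = seq_len(config$n_rooms),
                      day = seq_len(config$horizon_days))
  bins <- bins[order(bins$day, bins$room), , drop = FALSE]
  nb <- nrow(bins)
  if ((nb + 1)^n > 5e5) stop("instance too large for brute force", call. = FALSE)
  bin_surg <- rep(NA_integer_, nb)
  if (formulation == "MSSP") {
    stopifnot(!is.null(allocation))
    bin_surg <- allocation$surgeon_id[match(paste(bins$day, bins$room),
                                            paste(allocation$day, allocation$room))]
  }
  best <- Inf
  for (code in 0:((nb + 1)^n - 1)) {
    asg <- integer(n)  # 0 = unscheduled
    c0 <- code
    for (i in seq_len(n)) { asg[i] <- c0 %% (nb + 1); c0 <- c0 %/% (nb + 1) }
    if (any(cases$high_priority & asg == 0L)) next
    ok <- TRUE
    for (i in which(asg > 0L)) {
      d <- bins$day[asg[i]]
      if (!availability$available[cases$surgeon_id[i], d]) { ok <- FALSE; break }
      if (formulation == "MSSP" &&
          (is.na(bin_surg[asg[i]]) || bin_surg[asg[i]] != cases$surgeon_id[i])) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    # capacity and Split structure
    occ <- integer(nb)
    for (b in which(tabulate(asg, nb) > 0L))
      occ[b] <- sum(w[asg == b]) + g * (sum(asg == b) - 1L)
    if (any(occ > cap)) next
    if (formulation == "Split") {
      viol <- FALSE
      for (b in seq_len(nb))
        if (length(unique(cases$surgeon_id[asg == b])) > 2L) { viol <- TRUE; break }
      if (!viol) for (d in unique(bins$day)) {
        db <- which(bins$day == d)
        for (h in unique(cases$surgeon_id))
          if (sum(vapply(db, function(b) h %in% cases$surgeon_id[asg == b],
                         logical(1))) > 1L) { viol <- TRUE; break }
      }
      if (viol) next
    }
    # contiguous-packing bound: the timetable can only add waits, so skip
    # assignments whose bound already loses
    sb <- sum(vapply(seq_len(nb), function(b)
      if (occ[b] == 0L) Rb
      else if (occ[b] <= Rb) Rb - occ[b]
      else config$lambda_overtime * (occ[b] - Rb), numeric(1)))
    if (sb >= best) next
    cost <- oracle_plan_cost(asg, cases$surgeon_id, w, bins, Rb, g, cap,
                             config$lambda_overtime,
                             allow_cross_room = formulation == "Any")
    if (!is.null(cost) && cost < best) best <- cost
  }
  best * config$block_minutes
}

# minimal-cost timetable of a fixed assignment; enumerates execution orders
# when a surgeon's cases span rooms within a day, otherwise packs each room
# contiguously
oracle_plan_cost <- function(asg, surg, w, bins, Rb, g, cap, lambda,
                             allow_cross_room) {
  total <- 0
  for (d in unique(bins$day)) {
    db <- which(bins$day == d)
    items <- which(asg %in% db)
    spans <- any(vapply(unique(surg[items]), function(h)
      length(unique(asg[items][surg[items] == h])) > 1L, logical(1)))
    if (spans && !allow_cross_room) return(NULL)
    if (!spans) {
      for (b in db) {
        ib <- items[asg[items] == b]
        S <- if (length(ib)) sum(w[ib]) + g * (length(ib) - 1L) else 0L
        total <- total + if (S == 0L) Rb else if (S <= Rb) Rb - S else lambda * (S - Rb)
      }
    } else {
      best_day <- Inf
      perms <- perms_of(items)
      for (p in seq_len(nrow(perms))) {
        room_ready <- stats::setNames(rep(0L, length(db)), db)
        surg_free <- integer(max(surg))
        placed <- list()
        overflow <- FALSE
        for (i in perms[p, ]) {
          b <- as.character(asg[i])
          s <- max(room_ready[[b]], surg_free[surg[i]])
          e <- s + w[i]
          if (e > cap) { overflow <- TRUE; break }
          room_ready[[b]] <- e + g
          surg_free[surg[i]] <- e
          placed[[length(placed) + 1L]] <- c(asg[i], s, e)
        }
        if (overflow) next
        dc <- 0
        for (b in db) {
          pv <- Filter(function(z) z[1L] == b, placed)
          if (!length(pv)) { dc <- dc + Rb; next }
          se <- do.call(rbind, pv)
          se <- se[order(se[, 2L]), , drop = FALSE]
          last_end <- max(se[, 3L])
          busy <- sum(pmin(se[, 3L], Rb) - pmin(se[, 2L], Rb))
          if (nrow(se) > 1L) {
            ee <- se[-nrow(se), 3L]
            busy <- busy + sum(pmin(ee + g, Rb) - pmin(ee, Rb))
          }
          dc <- dc + max(0L, last_end - Rb) * lambda + (Rb - busy)
        }
        best_day <- min(best_day, dc)
      }
      if (!is.finite(best_day)) return(NULL)
      total <- total + best_day
    }
  }
  total
}

perms_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (k in seq_along(v))
    out <- rbind(out, cbind(v[k], perms_of(v[-k])))
  out
}

#' Generate the deterministic toy fixture bundle
#'
#' Writes a small case list (6 cases, predictions already set), a toy
#' 2-room / 1-day configuration and the exhaustively enumerated optimal
#' objective of each formulation -- the ground truth the test suite checks
#' the solvers against. Byte-identical for identical seeds.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return invisibly, the files written.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- schedule_config(n_rooms = 2L, n_surgeons = 2L, horizon_days = 1L,
                         block_minutes = 15L, regular_day_minutes = 240L,
                         max_overtime_minutes = 60L, cleaning_minutes = 15L,
                         waitlist_size = 6L, seed = seed)
  model <- duration_model(meanlog = c(TKA = log(60), THA = log(70)),
                          sdlog = c(TKA = 0.35, THA = 0.35))
  wl <- generate_waitlist(6L, model, n_surgeons = 2L, p_high = 0,
                          seed = derive_seed(seed, 0L, "fixtures"))
  wl <- predict_noisy_oracle(wl, noise_sigma = 10, floor = 15,
                             seed = derive_seed(seed, 1L, "fixtures"))
  av <- surgeon_availability(list(integer(0), integer(0)), cfg)
  alloc <- allocate_room_days(av, cfg, seed = seed)
  optima <- do.call(rbind, lapply(c("Any", "Split", "MSSP"), function(fo) {
    data.frame(formulation = fo,
               optimum_min = brute_force_objective(
                 wl, cfg, av, fo,
                 allocation = if (fo == "MSSP") alloc else NULL))
  }))
  files <- c(cases = file.path(dir, "toy_cases.csv"),
             config = file.path(dir, "toy_config.yaml"),
             allocation = file.path(dir, "toy_allocation.csv"),
             optima = file.path(dir, "toy_optima.csv"))
  write_waitlist(wl, files[["cases"]])
  save_config(cfg, files[["config"]])
  utils::write.csv(as.data.frame(alloc), files[["allocation"]], row.names = FALSE)
  utils::write.csv(optima, files[["optima"]], row.names = FALSE)
  invisible(files)
}

#' Write a reproducibility manifest for a simulation run
#'
#' Records everything needed to replay the run bit-for-bit: the full
#' configuration echo, the master seed, each week's derived stream seeds,
#' the artifact list and the package version.
#'
#' @param sim a [simulation_config()].
#' @param out_dir directory the manifest (and artifacts) live in.
#' @param files character vector of artifact paths.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(sim, out_dir, files = character(0)) {
  stopifnot(inherits(sim, "simulation_config"))
  weeks <- seq_len(sim$weeks)
  manifest <- list(
    tool = "orsched",
    version = as.character(utils::packageVersion("orsched")),
    master_seed = sim$master_seed,
    config = list(weeks = sim$weeks, arms = sim$arms,
                  formulations = sim$formulations,
                  granularities = sim$granularities,
                  waitlist_sizes = sim$waitlist_sizes,
                  p_high = sim$p_high, policy = sim$policy,
                  schedule = unclass(sim$base_config),
                  duration_model = list(
                    procedures = sim$model$procedures,
                    meanlog = as.list(sim$model$meanlog),
                    sdlog = as.list(sim$model$sdlog),
                    p_tka = sim$model$p_tka,
                    predictor = sim$model$predictor,
                    noise_sigma = as.list(sim$model$noise_sigma),
                    buffer = sim$model$buffer,
                    floor_minutes = sim$model$floor_minutes)),
    week_seeds = lapply(weeks, function(wk)
      list(week = wk,
           waitlist = derive_seed(sim$master_seed, wk, "waitlist"),
           availability = derive_seed(sim$master_seed, wk, "availability"),
           prediction = derive_seed(sim$master_seed, wk, "prediction"),
           allocation = derive_seed(sim$master_seed, wk, "allocation"))),
    artifacts = as.character(files))
  path <- file.path(out_dir, "manifest.json")
  manifest$config$schedule$solver_time_limit <-
    if (is.finite(sim$base_config$solver_time_limit))
      sim$base_config$solver_time_limit else "Inf"
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
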