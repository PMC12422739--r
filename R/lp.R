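#' Export a model in LP text format (debugging aid)
#'
#' Writes the time-indexed integer program of an `or_model` in CPLEX LP
#' format so small instances can be inspected or fed to an external solver.
#' Variables `x_c<i>_b<j>_s<t>` place case `i` in room-day `j` at start
#' block `t`; per-room-day `ot_`/`idle_` variables carry the objective.
#' Two deliberate simplifications keep the export linear and compact: a
#' cleaning block is reserved after every case (including the last), and
#' idle time is lower-bounded rather than defined by equality -- both are
#' tight at any optimum.
#'
#' @param model an [build_model()] result.
#' @param path output path (`.lp`).
#' @param max_vars guard against accidentally exporting a huge grid.
#' @return the path, invisibly.
#' @export
write_lp <- function(model, path, max_vars = 200000L) {
  stopifnot(inherits(model, "or_model"))
  cfg <- model$config
  w <- model$duration_blocks
  g <- cleaning_blocks(cfg)
  Rb <- regular_blocks(cfg)
  cap <- day_cap_blocks(cfg)
  bins <- model$bins
  n <- nrow(model$cases)
  av <- model$availability$available

  feas_bin <- function(i, j) {
    if (!av[model$cases$surgeon_id[i], bins$day[j]]) return(FALSE)
    if (model$formulation == "MSSP") {
      s <- bins$surgeon_id[j]
      return(!is.na(s) && s == model$cases$surgeon_id[i])
    }
    TRUE
  }
  vars <- list()
  for (i in seq_len(n)) for (j in seq_len(nrow(bins))) {
    if (!feas_bin(i, j)) next
    smax <- cap - w[i]
    if (smax < 0L) next
    vars[[length(vars) + 1L]] <- data.frame(i = i, j = j, s = 0:smax)
  }
  vars <- do.call(rbind, vars)
  if (is.null(vars) || !nrow(vars)) stop("model has no feasible placement", call. = FALSE)
  if (nrow(vars) > max_vars)
    stop(sprintf("LP export would need %d variables (> max_vars); use a smaller instance",
                 nrow(vars)), call. = FALSE)
  vname <- sprintf("x_c%d_b%d_s%d", vars$i, vars$j, vars$s)

  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("\\ %s weekly scheduling model, %d cases, %d room-days, %d-min blocks",
     model$formulation, n, nrow(bins), cfg$block_minutes)
  wl("Minimize")
  obj <- c(sprintf(" %g ot_b%d", cfg$lambda_overtime, bins$bin),
           sprintf(" 1 idle_b%d", bins$bin))
  wl(" obj:%s", paste0(" +", obj, collapse = ""))
  wl("Subject To")
  for (i in seq_len(n)) {
    sel <- vname[vars$i == i]
    if (!length(sel)) {
      if (model$cases$high_priority[i])
        stop_infeasible(sprintf("high-priority case %s has no feasible placement",
                                model$cases$case_id[i]), "availability/capacity")
      next
    }
    wl(" assign_c%d: %s %s 1", i, paste(sel, collapse = " + "),
       if (model$cases$high_priority[i]) "=" else "<=")
  }
  for (j in seq_len(nrow(bins))) for (tau in 0:(cap - 1L)) {
    sel <- vars$j == j & vars$s <= tau & tau < vars$s + w[vars$i] + g
    if (any(sel))
      wl(" room_b%d_t%d: %s <= 1", j, tau, paste(vname[sel], collapse = " + "))
  }
  for (h in unique(model$cases$surgeon_id)) for (d in unique(bins$day)) {
    jd <- bins$bin[bins$day == d]
    for (tau in 0:(cap - 1L)) {
      sel <- model$cases$surgeon_id[vars$i] == h & vars$j %in% jd &
        vars$s <= tau & tau < vars$s + w[vars$i]
      if (sum(sel) > 1L)
        wl(" surgeon_h%d_d%d_t%d: %s <= 1", h, d, tau,
           paste(vname[sel], collapse = " + "))
    }
  }
  if (model$formulation == "Split") {
    hs <- sort(unique(model$cases$surgeon_id))
    for (k in seq_len(nrow(vars)))
      wl(" link_%s: %s - y_h%d_b%d <= 0", vname[k], vname[k],
         model$cases$surgeon_id[vars$i[k]], vars$j[k])
    for (j in seq_len(nrow(bins)))
      wl(" room_share_b%d: %s <= 2", j,
         paste(sprintf("y_h%d_b%d", hs, j), collapse = " + "))
    for (h in hs) for (d in unique(bins$day))
      wl(" one_room_h%d_d%d: %s <= 1", h, d,
         paste(sprintf("y_h%d_b%d", h, bins$bin[bins$day == d]), collapse = " + "))
  }
  # overtime: ot_j >= (end - Rb) of every placed case ending past the day
  for (k in which(vars$s + w[vars$i] > Rb))
    wl(" ot_%s: %d %s - ot_b%d <= 0", vname[k],
       vars$s[k] + w[vars$i[k]] - Rb, vname[k], vars$j[k])
  # idle: idle_j >= Rb - occupied regular blocks
  for (j in seq_len(nrow(bins))) {
    sel <- which(vars$j == j)
    occ <- pmin(vars$s[sel] + w[vars$i[sel]] + g, Rb) - pmin(vars$s[sel], Rb)
    keep <- occ > 0L
    if (any(keep))
      wl(" idle_b%d: %s + idle_b%d >= %d", j,
         paste(sprintf("%d %s", occ[keep], vname[sel][keep]), collapse = " + "),
         j, Rb)
    else
      wl(" idle_b%d: idle_b%d >= %d", j, j, Rb)
  }
  wl("Bounds")
  for (j in seq_len(nrow(bins))) {
    wl(" 0 <= ot_b%d", j)
    wl(" 0 <= idle_b%d", j)
  }
  wl("Binaries")
  writeLines(paste(" ", vname), con)
  if (model$formulation == "Split") {
    hs <- sort(unique(model$cases$surgeon_id))
    for (j in seq_len(nrow(bins)))
      writeLines(paste(" ", sprintf("y_h%d_b%d", hs, j)), con)
  }
  wl("End")
  invisible(path)
}
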