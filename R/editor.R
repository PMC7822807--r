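#' Cord rest-length edit command
#'
#' Scriptable counterpart of the interactive cord editor: scale the rest
#' length of a single cord, of one of the four anatomical groups
#' (anterior/posterior leaflet x anterolateral/posteromedial tip), or of all
#' cords at once. Edits are multiplicative on the current rest length, so
#' scaling by `f` then `1/f` restores the original. An absolute-set variant
#' is available via `absolute = TRUE` for reproducibility.
#'
#' @param scope `"single"`, `"group"` or `"all"`.
#' @param target cord index (`single`), group label (`group`), or `NULL`
#'   (`all`).
#' @param factor positive multiplier on l0 (or the absolute l0 value when
#'   `absolute = TRUE`).
#' @param absolute set l0 to `factor` instead of multiplying.
#' @return An object of class `edit_command`.
#' @export
edit_command <- function(scope = c("single", "group", "all"), target = NULL,
                         factor = 1, absolute = FALSE) {
  scope <- match.arg(scope)
  stopifnot(factor > 0)
  if (scope == "single") stopifnot(is.numeric(target), length(target) == 1)
  if (scope == "group") stopifnot(is.character(target), length(target) == 1)
  structure(list(scope = scope, target = target, factor = factor,
                 absolute = isTRUE(absolute)),
            class = "edit_command")
}

cord_groups <- function() {
  c("anterior-anterolateral", "anterior-posteromedial",
    "posterior-anterolateral", "posterior-posteromedial")
}

#' Apply an edit command to a cord set
#'
#' Updates `rest_length` for every cord in scope and leaves all other cords
#' untouched. Safe to apply between simulation steps: the solver reads the
#' new rest lengths at its next projection without any state reset.
#'
#' @param cordset a [cord_set()].
#' @param cmd an [edit_command()].
#' @return The updated cord set.
#' @export
apply_edit <- function(cordset, cmd) {
  stopifnot(inherits(cordset, "cord_set"), inherits(cmd, "edit_command"))
  cd <- cordset$cords
  sel <- switch(cmd$scope,
    all = rep(TRUE, nrow(cd)),
    group = {
      if (!cmd$target %in% cord_groups())
        stop("unknown cord group '", cmd$target, "'; expected one of: ",
             paste(cord_groups(), collapse = ", "))
      cd$group == cmd$target
    },
    single = {
      if (cmd$target < 1 || cmd$target > nrow(cd))
        stop("cord index ", cmd$target, " out of range [1, ", nrow(cd), "]")
      seq_len(nrow(cd)) == cmd$target
    })
  cd$rest_length[sel] <- if (cmd$absolute) cmd$factor else
    cd$rest_length[sel] * cmd$factor
  cordset$cords <- cd
  cordset
}

#' Switch the force fields between closure and opening
#'
#' Negates the phase sign; pressure and velocity magnitudes are unchanged.
#' Applying it twice restores the original phase.
#'
#' @param phase a [force_phase()].
#' @return The phase with `phase_sign` negated.
#' @export
switch_phase <- function(phase) {
  stopifnot(inherits(phase, "force_phase"))
  phase$phase_sign <- -phase$phase_sign
  phase
}

#' Run a scripted editing session
#'
#' Headless counterpart of the interactive workflow: the closure simulation
#' runs and each scheduled command — a cord edit or a phase switch — is
#' applied at its simulation time without resetting the state (set
#' `restart = TRUE` to re-run from the open state after each edit instead).
#' After each command and at the end, a deviation snapshot against the
#' supplied tracings (and a prolapse check) is recorded.
#'
#' @param scene a `valve_scene`.
#' @param script list of commands; each element is
#'   `list(t =, command = edit_command)` or `list(t =, switch_phase = TRUE)`.
#'   Times must be non-decreasing.
#' @param config a [solver_config()].
#' @param phase starting [force_phase()].
#' @param tracings optional `tracing_set` for deviation snapshots.
#' @param restart re-run closure from the open state after each edit.
#' @return An object of class `mv_session`: fields `sim` (final
#'   [simulate_until_steady()] result), `snapshots` (one row per command plus
#'   the final state: time, command label, deviation statistics, prolapse
#'   flag), `cords` (edited cord set).
#' @export
run_session <- function(scene, script = list(), config = solver_config(),
                        phase = force_phase(), tracings = NULL,
                        restart = FALSE) {
  times <- vapply(script, function(s) s$t, numeric(1))
  if (is.unsorted(times)) stop("run_session: script times must be non-decreasing")
  constraints <- build_constraints(scene$mesh, scene$material)
  state <- sim_state(scene$mesh)
  log <- NULL
  snapshots <- list()

  snap <- function(state, label) {
    dev <- if (!is.null(tracings))
      evaluate_deviation(state$pos, scene$mesh$triangles, tracings) else NULL
    pro <- if (length(scene$mesh$free_edge_ids) > 0)
      detect_prolapse(state$pos, scene$mesh, scene$contour) else NULL
    row <- data.frame(time = state$t, command = label,
                      prolapse = if (is.null(pro)) NA else pro$prolapse,
                      max_height = if (is.null(pro)) NA_real_ else
                        pro$max_height)
    if (!is.null(dev))
      row <- cbind(row, data.frame(min_d = dev$min_d, med_d = dev$med_d,
                                   max_d = dev$max_d, avg_d = dev$avg_d,
                                   sd_d = dev$sd_d))
    row
  }

  for (cmd in script) {
    n_steps <- max(0L, round((cmd$t - state$t) / config$dt))
    if (n_steps > 0) {
      res <- xpbd_run(state, scene, constraints, phase, config, n_steps)
      state <- res$state
      log <- rbind(log, res$log)
    }
    if (isTRUE(cmd$switch_phase)) {
      phase <- switch_phase(phase)
      label <- "switch_phase"
    } else {
      scene$cords <- apply_edit(scene$cords, cmd$command)
      label <- paste0("edit:", cmd$command$scope,
                      if (!is.null(cmd$command$target))
                        paste0(":", cmd$command$target) else "",
                      ":x", signif(cmd$command$factor, 6))
      if (restart) state <- sim_state(scene$mesh)
    }
    snapshots[[length(snapshots) + 1]] <- snap(state, label)
  }

  sim <- simulate_until_steady(scene, phase, config, state = state,
                               constraints = constraints)
  sim$log <- rbind(log, sim$log)
  snapshots[[length(snapshots) + 1]] <- snap(sim$state, "final")

  structure(list(sim = sim,
                 snapshots = do.call(rbind, snapshots),
                 cords = scene$cords),
            class = "mv_session")
}

#' @export
print.mv_session <- function(x, ...) {
  cat("mv_session\n")
  print(x$snapshots, row.names = FALSE)
  invisible(x)
}
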