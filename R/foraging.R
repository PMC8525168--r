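# Foraging economics, evaluated once per phase as closed-form aggregates:
# encounter -> detection -> learning-discounted handling -> patch cap ->
# proportional competition scaling.

#' Maximum encounterable items in a foraging phase
#'
#' `N = A * T * (1 + E)`: an individual moving only in the obligatory
#' (every-second) time steps (`E = 0`) encounters half of what a maximally
#' explorative individual (`E = 1`) does.
#'
#' @param abundance Resource abundance `A` (items per time step), `>= 0`.
#' @param phase_length Phase duration `T` in time steps, `>= 0`.
#' @param exploration Expressed exploration tendency `E` in `[0, 1]`.
#' @return Non-negative real; vectorised over its arguments.
#' @examples
#' max_encounters(5, 25, 1) # 250
#' max_encounters(5, 25, 0) # 125, exactly half
#' @export
max_encounters <- function(abundance, phase_length, exploration) {
  abundance * phase_length * (1 + exploration)
}

#' Detected items after the speed/thoroughness trade-off
#'
#' `N' = N * (1 - (1 - C) * E)`: fast exploration lowers detection
#' thoroughness, the more so the harder items are to find (low `C`).
#' With `C = 1` or `E = 0` nothing is lost.
#'
#' @param n_max Encounter count `N` from [max_encounters()].
#' @param detectability Resource detectability `C` in `[0, 1]`.
#' @param exploration Expressed exploration tendency `E` in `[0, 1]`.
#' @return Non-negative real; vectorised.
#' @examples
#' detected_items(250, 0.5, 1) # 125
#' detected_items(250, 0.5, 0) # 250
#' @export
detected_items <- function(n_max, detectability, exploration) {
  n_max * (1 - (1 - detectability) * exploration)
}

# round half away from zero (inputs are non-negative counts)
round_half_up <- function(x) floor(x + 0.5)

#' Learning-discounted handling of detected items
#'
#' Processing the `j`-th item of a resource type (counted over the whole
#' lifetime, so experience carries across phases and patches) yields value
#' fraction `max(0, 1 - (H - 1) / (j * L))`: a learning curve that rises
#' towards 1 at a decelerating rate. For `H = 1` every item counts in full;
#' for `L = 0` and `H > 1` the fraction is 0 (a non-learner can never crack
#' a hard resource, the limit as `L -> 0+`). The sum over the current
#' phase's `n_items` items is evaluated in closed form via harmonic numbers
#' (`digamma`), which matches the literal per-item loop to well below 1e-9.
#'
#' @param n_items Integer count of items handled this phase (the rounded
#'   detected count).
#' @param handling_time Resource handling time `H >= 1`.
#' @param learning Expressed learning ability `L` in `[0, 1]`.
#' @param prior_experience Cumulative items of this resource already
#'   handled this lifetime (the offset of the practice index `j`).
#' @return A list with `handled` (the summed value fractions) and
#'   `new_experience` (`prior_experience + n_items`); vectorised.
#' @examples
#' handled_sum(125, 1, 0, 0)$handled    # 125: no learning needed
#' handled_sum(125, 300, 1, 0)$handled  # 0: 299 practice items still missing
#' @export
handled_sum <- function(n_items, handling_time, learning, prior_experience = 0) {
  k <- max(length(n_items), length(handling_time), length(learning),
           length(prior_experience))
  n <- rep_len(as.numeric(n_items), k)
  H <- rep_len(as.numeric(handling_time), k)
  L <- rep_len(as.numeric(learning), k)
  prior <- rep_len(as.numeric(prior_experience), k)

  handled <- numeric(k)
  easy <- H <= 1
  handled[easy] <- n[easy]
  hard <- !easy & L > 0 & n > 0
  if (any(hard)) {
    theta <- (H[hard] - 1) / L[hard]      # j must exceed theta to pay
    j2 <- prior[hard] + n[hard]
    jmin <- pmax(prior[hard] + 1, floor(theta) + 1)
    pos <- j2 >= jmin
    val <- numeric(sum(hard))
    if (any(pos)) {
      val[pos] <- (j2[pos] - jmin[pos] + 1) -
        theta[pos] * (digamma(j2[pos] + 1) - digamma(jmin[pos]))
    }
    handled[hard] <- pmax(val, 0)
  }
  list(handled = handled, new_experience = prior + n)
}

#' Per-patch resource cap
#'
#' `Rmax = T * A * N_individuals / Phi`: the total amount of a resource a
#' patch can yield in one phase, scaled by the competition factor `Phi`.
#' The fixed carrying capacity enters, not the current occupancy.
#'
#' @param phase_length The phase's own duration `T`.
#' @param abundance Resource abundance `A` in the patch.
#' @param carrying_capacity Patch carrying capacity `N_individuals`.
#' @param competition_factor `Phi > 0`.
#' @return Non-negative real; vectorised.
#' @examples
#' patch_resource_cap(25, 5, 100, 2) # 6250
#' @export
patch_resource_cap <- function(phase_length, abundance, carrying_capacity,
                               competition_factor) {
  phase_length * abundance * carrying_capacity / competition_factor
}

#' Proportional competition scaling
#'
#' If the summed pre-competition collection of a resource across a patch's
#' occupants exceeds the patch cap, every occupant's amount is scaled by
#' `cap / sum` (the resource is fully depleted and shares shrink
#' proportionally); otherwise amounts pass through unchanged.
#'
#' @param handled_by_individual Numeric vector of per-occupant handled
#'   amounts of one resource in one patch.
#' @param cap The patch's cap for that resource ([patch_resource_cap()]).
#' @return Numeric vector of post-competition amounts.
#' @examples
#' apply_competition(c(6, 4), cap = 5) # scaled by 0.5
#' @export
apply_competition <- function(handled_by_individual, cap) {
  tot <- sum(handled_by_individual)
  if (tot <= cap || tot == 0) return(handled_by_individual)
  handled_by_individual * (cap / tot)
}

#' Run one foraging phase over the whole world
#'
#' For every patch and every resource present there, computes each
#' occupant's encounter, detection and learning-discounted handling using
#' its expressed traits and lifetime experience ledger, then applies the
#' patch cap and proportional competition across the patch's current
#' occupants. Post-competition value (`amount * V`) accrues to each
#' individual's `v_total`; experience ledgers advance by the rounded
#' detected count (practice happens regardless of competitive forfeiture).
#'
#' @param world World list (see [init_world()]).
#' @param cfg Validated `sim_config`.
#' @param phase `"before"` or `"after"`; selects the phase duration.
#' @param diagnostics If `TRUE`, attach a `diagnostics` tibble to the
#'   returned world with one row per (patch, resource): the cap, the
#'   pre-competition total and the post-competition total.
#' @return The updated world.
#' @export
forage_phase <- function(world, cfg, phase = c("before", "after"),
                         diagnostics = FALSE) {
  phase <- match.arg(phase)
  T_phase <- if (phase == "before") cfg$t_before else cfg$t_after
  pop <- world$pop
  n <- pop_size(pop)
  if (n == 0) return(world)

  A_mat <- abundance_matrix(cfg)
  ptype <- cfg$patch_type_assignment[pop$patch]
  res <- cfg$resources
  diag_rows <- if (diagnostics) vector("list", nrow(res)) else NULL

  for (r in seq_len(nrow(res))) {
    A_ind <- A_mat[ptype, r]
    if (all(A_ind == 0)) next
    n_enc <- max_encounters(A_ind, T_phase, pop$E)
    n_det <- detected_items(n_enc, res$detectability[r], pop$E)
    n_items <- round_half_up(n_det)
    hs <- handled_sum(n_items, res$handling_time[r], pop$L, pop$exper[, r])

    cap_patch <- patch_resource_cap(
      T_phase, A_mat[cfg$patch_type_assignment, r],
      cfg$n_individuals, cfg$competition_factor)
    tot_patch <- numeric(cfg$n_patches)   # empty patches contribute 0
    sums <- rowsum(hs$handled, pop$patch)
    tot_patch[as.integer(rownames(sums))] <- sums[, 1]
    scale_patch <- rep(1, cfg$n_patches)
    binds <- tot_patch > cap_patch & tot_patch > 0
    scale_patch[binds] <- cap_patch[binds] / tot_patch[binds]

    pop$vtot <- pop$vtot + hs$handled * scale_patch[pop$patch] * res$value[r]
    pop$exper[, r] <- hs$new_experience
    if (diagnostics) {
      diag_rows[[r]] <- tibble::tibble(
        phase = phase, patch = seq_len(cfg$n_patches),
        resource_id = res$resource_id[r],
        cap = cap_patch, pre_total = tot_patch,
        post_total = tot_patch * scale_patch)
    }
  }
  world$pop <- pop
  if (diagnostics) world$diagnostics <- dplyr::bind_rows(diag_rows)
  world
}
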