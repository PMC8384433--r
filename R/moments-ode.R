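# Tip moments for the interaction-aware families (DD_exp, DD_lin, MC),
# propagated along the event timeline. Within an interval the alive set,
# regimes and sympatry matrix A are constant and the mean/covariance obey
#
#   dm/dt = R m,     dV/dt = R V + V R' + D
#
# where for MC the drift matrix has rows R_jj = -S_g(j)*(1 - w_jj),
# R_jl = S_g(j)*w_jl with weights w_jl = A_jl / sum_l A_jl over same-regime
# lineages (self-inclusive), and D = sigma2*I; for DD R = 0 and D is
# diagonal with sigma0^2*exp(r_g*d_j) (DD_exp) or sigma0^2 + b_g*d_j
# (DD_lin). Because the MC weight rows sum to one, R has zero row sums and
# the mean stays at z0 for every family here; only V needs integration.
# With R = 0 and D constant on the interval the V update is exact
# (V += D*dt); the genuinely coupled MC case is integrated by fixed-step
# classical Runge-Kutta with the step chosen so that |S|*h <= rk_h (the
# integrator is cross-checked against deSolve and closed forms in the
# test suite). At a branching both daughters copy the parent's row/column.

#' Timeline-propagated tip moments for DD and MC models
#'
#' @param model `"DDexp"`, `"DDlin"` or `"MC"`.
#' @param params Parameter list (see [model_params()]).
#' @param timeline An [build_event_timeline()] object (carries the tree,
#'   regimes and sympatry structure).
#' @param interaction `"within"` (as the models are defined) or `"across"`
#'   (all sympatric lineages interact; the regime sets only the focal
#'   coefficient).
#' @param rk_h Dimensionless Runge-Kutta step control for MC:
#'   substeps are chosen so that `max|S| * h <= rk_h` (default 0.02).
#' @return List with `m` and `V` over tips (tip-label order).
#' @export
tip_moments_ode <- function(model, params, timeline,
                            interaction = c("within", "across"),
                            rk_h = 0.02) {
  interaction <- match.arg(interaction)
  model <- match.arg(model, c("DDexp", "DDlin", "MC"))
  tl <- timeline
  ntip <- tl$ntip
  tree <- tl$tree
  p <- params
  ab <- if (tl$regimes) unique(unlist(lapply(tl$intervals, `[[`, "regime"))) else "A"
  per_regime <- function(x, reg) {
    if (length(x) == 1L) rep(unname(x), length(reg)) else unname(x[reg])
  }
  V <- matrix(0, ntip, ntip)
  slot <- integer(ntip + tree$Nnode)
  first <- tl$intervals[[1]]
  slot[first$lineages] <- c(1L, 2L)
  nslot <- 2L
  for (iv in tl$intervals) {
    newbies <- which(slot[iv$lineages] == 0L)
    reused <- integer(0)
    for (nb in newbies) {
      l <- iv$lineages[nb]
      par_slot <- slot[iv$parent[nb]]
      if (par_slot == 0L) stop_("internal error: unknown parent lineage")
      if (!par_slot %in% reused) {
        # first daughter inherits the parent's slot (row/col already correct)
        slot[l] <- par_slot
        reused <- c(reused, par_slot)
      } else {
        nslot <- nslot + 1L
        slot[l] <- nslot
        V[nslot, seq_len(nslot - 1L)] <- V[par_slot, seq_len(nslot - 1L)]
        V[seq_len(nslot - 1L), nslot] <- V[seq_len(nslot - 1L), par_slot]
        V[nslot, nslot] <- V[par_slot, par_slot]
        V[nslot, par_slot] <- V[par_slot, nslot] <- V[par_slot, par_slot]
      }
    }
    span <- iv$t1 - iv$t0
    if (span <= 0) next
    sl <- slot[iv$lineages]
    reg <- iv$regime
    if (model == "MC") {
      S <- per_regime(p$S, reg)
      s2 <- unname(p$sigma2)
      same <- outer(reg, reg, "==")
      Amask <- iv$A * (if (interaction == "within") same else 1)
      Vs <- V[sl, sl, drop = FALSE]
      blockwise <- if (interaction == "within") {
        all(Amask[same] == 1)
      } else {
        all(iv$A == 1) && length(unique(S)) == 1L
      }
      if (blockwise) {
        # complete within-group sympatry: the weight matrix is the
        # block-averaging projector P, so exp(S*(P-I)*t) and the noise
        # integral are exact in O(n^2)
        grp <- if (interaction == "within") match(reg, unique(reg)) else rep(1L, length(reg))
        Vs <- mc_blockwise_update(Vs, grp, S, s2, span)
      } else {
        W <- Amask / rowSums(Amask)
        R <- S * (W - diag(length(reg)))
        Smax <- max(abs(S), 1e-12)
        nst <- max(1L, ceiling(span * Smax / rk_h))
        h <- span / nst
        Rt <- t(R)
        for (s in seq_len(nst)) {
          f <- function(M) { out <- R %*% M + M %*% Rt; diag(out) <- diag(out) + s2; out }
          k1 <- f(Vs)
          k2 <- f(Vs + h / 2 * k1)
          k3 <- f(Vs + h / 2 * k2)
          k4 <- f(Vs + h * k3)
          Vs <- Vs + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        }
      }
      V[sl, sl] <- Vs
    } else {
      dsym <- if (interaction == "within") iv$d else rowSums(iv$A)
      rate <- if (model == "DDexp") {
        unname(p$sigma2) * exp(per_regime(p$r, reg) * dsym)
      } else {
        unname(p$sigma2) + per_regime(p$b, reg) * dsym
      }
      if (model == "DDlin" && any(rate < 0)) {
        stop_(sprintf("DD_lin rate is negative on interval [%.4g, %.4g]: parameters outside the admissible region",
                      iv$t0, iv$t1))
      }
      V[cbind(sl, sl)] <- V[cbind(sl, sl)] + rate * span
    }
    if (!all(is.finite(V[sl, sl]))) {
      stop_(sprintf("moment propagation produced non-finite values on interval [%.4g, %.4g]",
                    iv$t0, iv$t1))
    }
  }
  tip_slots <- slot[seq_len(ntip)]
  Vout <- V[tip_slots, tip_slots, drop = FALSE]
  Vout <- (Vout + t(Vout)) / 2
  dimnames(Vout) <- list(tree$tip.label, tree$tip.label)
  m <- stats::setNames(rep(unname(p$z0), ntip), tree$tip.label)
  list(m = m, V = Vout)
}

# Exact MC covariance update over one interval when every pair of
# interacting lineages is sympatric. With groups g (regimes), sizes q_g,
# the weight matrix is the projector P = blockdiag(J_g/q_g) and
# exp(R*t) = blockdiag(a_g*I + (b_g/q_g)*J_g) with a_g = exp(-S_g*t),
# b_g = 1 - a_g. The solution of dV/dt = RV + VR' + s2*I is
# V(t) = E V0 E' + Q with Q = blockdiag(s2*(phi_g*I + (t-phi_g)*J_g/q_g)),
# phi_g = (1 - exp(-2*S_g*t)) / (2*S_g) (limit t as S -> 0); the noise
# integral is block-diagonal because the diffusion matrix is diagonal.
mc_blockwise_update <- function(V, grp, S, s2, span) {
  n <- nrow(V)
  G <- max(grp)
  q <- tabulate(grp, G)
  Sg <- vapply(seq_len(G), function(g) S[match(g, grp)], numeric(1))
  a <- exp(-Sg * span)
  b <- 1 - a
  phi <- ifelse(abs(Sg) < 1e-12, span, (1 - exp(-2 * Sg * span)) / (2 * Sg))
  av <- a[grp]; bv <- b[grp]
  # group means of rows/columns and the grand block means
  memb <- matrix(0, n, G)
  memb[cbind(seq_len(n), grp)] <- 1
  wmemb <- sweep(memb, 2, q, "/")
  CM <- V %*% wmemb            # CM[i, h] = mean_{j in h} V[i, j]
  GM <- t(wmemb) %*% CM        # GM[g, h] = block mean
  CMe <- CM[, grp, drop = FALSE]
  RMe <- t(CMe)                # V symmetric
  GMe <- GM[grp, grp, drop = FALSE]
  Vn <- outer(av, av) * V + outer(av, bv) * CMe +
    outer(bv, av) * RMe + outer(bv, bv) * GMe
  diag(Vn) <- diag(Vn) + s2 * phi[grp]
  samegrp <- outer(grp, grp, "==")
  Vn <- Vn + samegrp * (s2 * (span - phi[grp]) / q[grp])
  Vn
}

# Precompiled MC covariance structure: slot bookkeeping, per-interval group
# and weight structure extracted once from the timeline so that repeated
# likelihood evaluations during fitting only redo the numerics.
mc_structure <- function(timeline, interaction = "within") {
  tl <- timeline
  ntip <- tl$ntip
  slot <- integer(ntip + tl$tree$Nnode)
  first <- tl$intervals[[1]]
  slot[first$lineages] <- c(1L, 2L)
  nslot <- 2L
  recs <- vector("list", length(tl$intervals))
  for (k in seq_along(tl$intervals)) {
    iv <- tl$intervals[[k]]
    copies <- NULL
    reused <- integer(0)
    for (nb in which(slot[iv$lineages] == 0L)) {
      l <- iv$lineages[nb]
      par_slot <- slot[iv$parent[nb]]
      if (!par_slot %in% reused) {
        slot[l] <- par_slot
        reused <- c(reused, par_slot)
      } else {
        nslot <- nslot + 1L
        slot[l] <- nslot
        copies <- rbind(copies, c(par_slot, nslot))
      }
    }
    reg <- iv$regime
    same <- outer(reg, reg, "==")
    Amask <- iv$A * (if (interaction == "within") same else 1)
    blockwise <- if (interaction == "within") all(Amask[same] == 1) else all(iv$A == 1)
    recs[[k]] <- list(span = iv$t1 - iv$t0, sl = slot[iv$lineages],
                      reg = reg, blockwise = blockwise,
                      grp = if (interaction == "within") match(reg, unique(reg))
                            else rep(1L, length(reg)),
                      W = if (!blockwise) Amask / rowSums(Amask) else NULL,
                      copies = copies)
  }
  list(records = recs, tip_slots = slot[seq_len(ntip)], ntip = ntip,
       labels = tl$tree$tip.label, interaction = interaction)
}

# Tip covariance under MC for a regime-named S vector, using a precompiled
# structure. Matches tip_moments_ode(..., "MC") exactly.
mc_cov <- function(st, S, sigma2, rk_h = 0.02) {
  ntip <- st$ntip
  V <- matrix(0, ntip, ntip)
  per_regime <- function(x, reg) {
    if (length(x) == 1L) rep(unname(x), length(reg)) else unname(x[reg])
  }
  for (rec in st$records) {
    if (!is.null(rec$copies)) {
      for (ci in seq_len(nrow(rec$copies))) {
        from <- rec$copies[ci, 1]; to <- rec$copies[ci, 2]
        V[to, seq_len(to - 1L)] <- V[from, seq_len(to - 1L)]
        V[seq_len(to - 1L), to] <- V[seq_len(to - 1L), from]
        V[to, to] <- V[from, from]
        V[to, from] <- V[from, to] <- V[from, from]
      }
    }
    if (rec$span <= 0) next
    sl <- rec$sl
    Sv <- per_regime(S, rec$reg)
    Vs <- V[sl, sl, drop = FALSE]
    if (rec$blockwise && (st$interaction == "within" || length(unique(Sv)) == 1L)) {
      Vs <- mc_blockwise_update(Vs, rec$grp, Sv, sigma2, rec$span)
    } else {
      R <- Sv * (rec$W - diag(length(Sv)))
      Smax <- max(abs(Sv), 1e-12)
      nst <- max(1L, ceiling(rec$span * Smax / rk_h))
      h <- rec$span / nst
      Rt <- t(R)
      for (s in seq_len(nst)) {
        f <- function(M) { out <- R %*% M + M %*% Rt; diag(out) <- diag(out) + sigma2; out }
        k1 <- f(Vs); k2 <- f(Vs + h / 2 * k1); k3 <- f(Vs + h / 2 * k2); k4 <- f(Vs + h * k3)
        Vs <- Vs + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    V[sl, sl] <- Vs
  }
  out <- V[st$tip_slots, st$tip_slots, drop = FALSE]
  out <- (out + t(out)) / 2
  dimnames(out) <- list(st$labels, st$labels)
  out
}

# Linear structure of DD_lin covariances: V = sigma2*Tm + sum_g b_g*H_g,
# precomputed once per (timeline, interaction) and reused across likelihood
# evaluations. Also records max d per regime for admissibility checks.
dd_lin_structure <- function(timeline, interaction = "within", alphabet = NULL) {
  ab <- alphabet %||% (if (timeline$regimes)
    sort(unique(unlist(lapply(timeline$intervals, `[[`, "regime")))) else "A")
  base <- tip_moments_ode("DDlin",
                          list(z0 = 0, sigma2 = 1,
                               b = stats::setNames(rep(0, length(ab)), ab)),
                          timeline, interaction = interaction)$V
  H <- lapply(ab, function(g) {
    b <- stats::setNames(rep(0, length(ab)), ab); b[g] <- 1
    # sigma2 = large so every interval stays admissible, then subtract
    tip_moments_ode("DDlin", list(z0 = 0, sigma2 = 1e6, b = b),
                    timeline, interaction = interaction)$V - 1e6 * base
  })
  dmax <- vapply(ab, function(g) {
    max(c(0, unlist(lapply(timeline$intervals, function(iv) {
      d <- if (interaction == "within") iv$d else rowSums(iv$A)
      d[iv$regime == g]
    }))))
  }, numeric(1))
  list(Tm = base, H = stats::setNames(H, ab), alphabet = ab, dmax = dmax)
}
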