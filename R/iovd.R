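## Monocular speed profile of the IOVD stimulus family, degrees/s.
##
## The stimulus oscillates in depth at `iovd_frequency`; the two modes pin
## down either the peak monocular speed (velocity_matched: v(t) =
## V sin(2 pi f t) with V = iovd_peak_speed) or the monocular displacement
## amplitude (displacement_matched: x(t) = A sin(2 pi f t), so v(t) =
## 2 pi f A cos(2 pi f t) with A = iovd_displacement_amplitude).
iovd_velocity <- function(t, params) {
  f <- params$iovd_frequency
  if (params$iovd_profile_mode == "velocity_matched") {
    params$iovd_peak_speed * sin(2 * pi * f * t)
  } else {
    (params$iovd_displacement_amplitude / 60) * 2 * pi * f * cos(2 * pi * f * t)
  }
}

iovd_peak_velocity <- function(params) {
  if (params$iovd_profile_mode == "velocity_matched") {
    params$iovd_peak_speed
  } else {
    (params$iovd_displacement_amplitude / 60) * 2 * pi * params$iovd_frequency
  }
}

## Resolve contrast polarities for one video frame. Interocular dot pairs
## whose centers are within `anticorr_radius` of each other, with both
## centers within one stripe height of a stripe border, must have opposite
## polarity. The constraint graph is bipartite (edges always join the two
## eyes), so each connected component is 2-colorable: the component root
## keeps its base polarity and parity with the root's eye fixes the rest.
resolve_polarity <- function(lx, ly, lbase, rx, ry, rbase, params, edges_y) {
  nl <- length(lx); nr <- length(rx)
  pol_l <- lbase; pol_r <- rbase
  if (nl == 0 || nr == 0) return(list(left = pol_l, right = pol_r))
  near_l <- near_border(ly, edges_y, params$stripe_height)
  near_r <- near_border(ry, edges_y, params$stripe_height)
  il <- which(near_l); ir <- which(near_r)
  if (!length(il) || !length(ir)) return(list(left = pol_l, right = pol_r))
  dx <- outer(lx[il], rx[ir], "-")
  dy <- outer(ly[il], ry[ir], "-")
  hit <- which(dx^2 + dy^2 <= params$anticorr_radius^2, arr.ind = TRUE)
  if (!nrow(hit)) return(list(left = pol_l, right = pol_r))
  ## combined indexing: left dots 1..nl, right dots nl+1..nl+nr
  a <- il[hit[, 1]]
  b <- nl + ir[hit[, 2]]
  adj <- split(c(b, a), c(a, b))
  side <- c(rep(1L, nl), rep(-1L, nr)) # +1 = left eye
  base <- c(pol_l, pol_r)
  visited <- logical(nl + nr)
  for (root in sort(unique(c(a, b)))) {
    if (visited[root]) next
    queue <- root
    visited[root] <- TRUE
    comp <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[as.character(v)]]
      nb <- nb[!visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
        comp <- c(comp, nb)
      }
    }
    pol_root <- base[root]
    for (v in comp) {
      p <- if (side[v] == side[root]) pol_root else -pol_root
      if (v <= nl) pol_l[v] <- p else pol_r[v - nl] <- p
    }
  }
  list(left = pol_l, right = pol_r)
}

near_border <- function(y, edges_y, stripe_height) {
  interior <- edges_y[-c(1, length(edges_y))]
  if (!length(interior)) return(rep(FALSE, length(y)))
  d <- vapply(y, function(yy) min(abs(yy - interior)), numeric(1))
  d <= stripe_height
}

## Shared engine behind iovd_sequence() and iovd_control_sequence().
iovd_engine <- function(params, coherence, seed, cue) {
  validate_stimulus_params(params)
  if (params$stripe_height <= 0) stop("stripe_height must be > 0", call. = FALSE)
  if (params$anticorr_radius < 0) stop("anticorr_radius must be >= 0", call. = FALSE)
  if (coherence < 0 || coherence > 1) stop("coherence must be in [0, 1]", call. = FALSE)

  nF <- n_frames(params)
  times <- frame_times(params)
  L <- lifetime_frames(params)
  bands <- stripe_bands(params)
  drift <- iovd_peak_velocity(params) * params$dot_lifetime
  closure <- 2 * drift
  fdx <- list(sig = c(-drift, drift), pos = c(-drift, drift),
              neg = c(-drift, drift))
  fr_rate <- params$frame_rate

  eyes <- c("left", "right")
  state <- list()
  id_counter <- 0L
  for (e in eyes) {
    eb <- bands[bands$eye == e, ]
    area_e <- sum(eb$area)
    ## even per-eye count (still within one dot of density * area) so the
    ## leftward/rightward noise split can be exactly balanced
    N <- 2L * as.integer(round(params$density * area_e / 2))
    n_sig <- as.integer(round(coherence * N))
    n_noise <- N - n_sig
    n_pos <- ceiling(n_noise / 2)
    n_neg <- n_noise - n_pos
    st <- with_seed(mix_seed(seed, match(e, eyes), 101L), {
      groups <- sample(c(rep("sig", n_sig), rep("pos", n_pos), rep("neg", n_neg)))
      pos <- place_dots(N, params, group = groups, closure = closure,
                        future_dx = fdx, bands = eb)
      q <- if (N > 0) as.integer(ceiling(N / L)) else 0L
      rank <- sample(N)
      spawn <- 1L - ((rank - 1L) %/% max(q, 1L))
      data.frame(
        id = id_counter + seq_len(N), x = pos$x, y = pos$y,
        group = groups, spawn = spawn,
        base_pol = sample(c(-1L, 1L), N, replace = TRUE),
        stringsAsFactors = FALSE
      )
    })
    id_counter <- id_counter + nrow(st)
    attr(st, "q") <- if (nrow(st) > 0) as.integer(ceiling(nrow(st) / L)) else 0L
    ## per-group kill bookkeeping for the deficit scheduler (see below)
    attr(st, "pools") <- c(sig = n_sig, pos = n_pos, neg = n_neg)
    attr(st, "killed") <- c(sig = 0, pos = 0, neg = 0)
    state[[e]] <- st
  }
  edges_y <- c(bands$lo, bands$hi[nrow(bands)])

  rows <- vector("list", 2L * nF)
  for (f in seq_len(nF)) {
    sl <- state$left; sr <- state$right
    pol <- resolve_polarity(sl$x, sl$y, sl$base_pol, sr$x, sr$y, sr$base_pol,
                            params, edges_y)
    v_now <- iovd_velocity(times[f], params)
    for (e in eyes) {
      st <- state[[e]]
      p <- if (e == "left") pol$left else pol$right
      role <- ifelse(st$group == "sig", "signal", "noise")
      stripe <- findInterval(st$y, edges_y, rightmost.closed = TRUE)
      s_eye <- if (e == "left") 1 else -1
      vx <- numeric(nrow(st))
      vx[st$group == "sig"] <- s_eye * v_now
      vx[st$group == "pos"] <- abs(v_now)
      vx[st$group == "neg"] <- -abs(v_now)
      rows[[2L * (f - 1L) + match(e, eyes)]] <- data.frame(
        frame = f, time = times[f], eye = e, id = st$id,
        x = st$x, y = st$y, polarity = p, role = role,
        age = f - st$spawn + 1L, stripe = stripe, vx = vx,
        stringsAsFactors = FALSE
      )
    }
    if (f == nF) break

    v <- v_now
    for (e in eyes) {
      st <- state[[e]]
      if (!nrow(st)) next
      s_eye <- if (e == "left") 1 else -1
      dx <- numeric(nrow(st))
      dx[st$group == "sig"] <- s_eye * v / fr_rate
      dx[st$group == "pos"] <- abs(v) / fr_rate
      dx[st$group == "neg"] <- -abs(v) / fr_rate
      st$x <- st$x + dx

      q <- attr(st, "q")
      pools <- attr(st, "pools")
      killed <- attr(st, "killed")
      r2 <- st$x^2 + st$y^2
      escaped <- which(r2 < params$aperture_inner^2 |
                         r2 > params$aperture_outer^2)
      ## dots that would exceed the lifetime on the next frame must die now
      expired <- which(st$spawn <= f + 1L - L)
      kill <- union(escaped, expired)
      for (g in st$group[kill]) killed[g] <- killed[g] + 1
      ## pad the kill set up to the fixed per-frame quota, always taking the
      ## group with the largest kill deficit (oldest dot within that group).
      ## The schedule depends only on group pool sizes, so both eyes kill
      ## identical group compositions every frame and the noise contribution
      ## to the interocular velocity difference cancels exactly.
      ord <- order(st$spawn, st$id)
      while (length(kill) < q) {
        deficit <- f * pools / L - killed
        avail <- setdiff(ord, kill)
        gs <- names(sort(deficit, decreasing = TRUE))
        picked <- FALSE
        for (g in gs) {
          cand <- avail[st$group[avail] == g]
          if (length(cand)) {
            kill <- c(kill, cand[1L])
            killed[g] <- killed[g] + 1
            picked <- TRUE
            break
          }
        }
        if (!picked) break
      }
      kill <- sort(kill)
      keep <- setdiff(seq_len(nrow(st)), kill)
      killed_groups <- st$group[kill]
      surv <- st[keep, , drop = FALSE]

      nb <- length(kill)
      eb <- bands[bands$eye == e, ]
      newdots <- with_seed(mix_seed(seed, f, match(e, eyes), 17L), {
        posn <- place_dots(nb, params, group = killed_groups,
                           existing_xy = cbind(surv$x, surv$y),
                           existing_group = surv$group,
                           closure = closure, future_dx = fdx, bands = eb)
        data.frame(
          id = id_counter + seq_len(nb), x = posn$x, y = posn$y,
          group = killed_groups, spawn = f + 1L,
          base_pol = sample(c(-1L, 1L), nb, replace = TRUE),
          stringsAsFactors = FALSE
        )
      })
      id_counter <- id_counter + nb
      st2 <- rbind(surv, newdots)
      attr(st2, "q") <- q
      attr(st2, "pools") <- pools
      attr(st2, "killed") <- killed
      state[[e]] <- st2
    }
  }
  frames <- do.call(rbind, rows)
  frames <- frames[order(frames$frame, frames$eye, frames$id), ]
  rownames(frames) <- NULL
  new_stereo_sequence(params, cue, coherence, frames,
                      data.frame(left_id = integer(0), right_id = integer(0)),
                      as.integer(seed))
}

#' Interocular-velocity-difference (IOVD) stimulus sequence
#'
#' Builds the IOVD dynamic random-dot stimulus: per-eye dot patterns are
#' decorrelated (independently placed), the display is partitioned into
#' horizontal stripes assigned alternately to the two eyes, and any
#' interocular dot pair falling close together near a stripe border is given
#' opposite contrast polarity. These three measures jointly eliminate
#' residual binocular-disparity (CD) leakage.
#'
#' Signal dots translate horizontally with equal and opposite velocity in the
#' two eyes (`v_L(t) = -v_R(t)`), following the configured oscillation
#' profile at `iovd_frequency` Hz. Each dot lives at most
#' `dot_lifetime * frame_rate` frames, and the same number of dots is
#' regenerated on every video frame so that visual transients are balanced.
#' Noise dots (fraction `1 - coherence` per eye) move at the same speed but
#' split as evenly as possible between leftward and rightward within each
#' eye, nulling their net contribution to the interocular velocity
#' difference.
#'
#' @inheritParams cd_sequence
#' @return A `stereo_sequence` with `cue = "IOVD"`.
#' @export
#' @examples
#' p <- stimulus_params(duration = 0.5)
#' s <- iovd_sequence(p, coherence = 1, seed = 1)
#' max_dot_persistence(s) # 6 frames = 50 ms at 120 Hz
iovd_sequence <- function(params, coherence = 1, seed = 1) {
  iovd_engine(params, coherence, seed, "IOVD")
}

#' IOVD control sequence (monocularly nulled motion)
#'
#' Identical to the IOVD stimulus except that within each eye equal numbers
#' of dots move leftward and rightward at every frame, so the monocular
#' motion energy is preserved while the binocular opponent-motion signal that
#' conveys MID is nulled.
#'
#' @inheritParams cd_sequence
#' @return A `stereo_sequence` with `cue = "IOVD_control"`.
#' @export
iovd_control_sequence <- function(params, seed = 1) {
  iovd_engine(params, 0, seed, "IOVD_control")
}

#' Interocular velocity-difference trace
#'
#' Per-frame difference between the mean signed horizontal dot velocity of
#' the left and right eyes, computed from within-lifetime frame-to-frame
#' displacements of persisting dots only.
#'
#' @param seq A `stereo_sequence` with cue `"IOVD"` or `"IOVD_control"`.
#' @return A `ts_trace` (times in s, values in degrees/s).
#' @export
iovd_trace <- function(seq) {
  if (!seq$cue %in% c("IOVD", "IOVD_control")) {
    stop("iovd_trace requires an IOVD or IOVD_control sequence", call. = FALSE)
  }
  fr <- sort(unique(seq$frames$frame))
  if (length(fr) < 2) stop("sequence too short for velocities", call. = FALSE)
  rate <- seq$params$frame_rate
  vals <- numeric(length(fr) - 1L)
  for (e in c("left", "right")) {
    sub <- seq$frames[seq$frames$eye == e, ]
    byf <- split(sub[, c("id", "x")], factor(sub$frame, levels = fr))
    s_eye <- if (e == "left") 1 else -1
    for (i in seq_along(fr)[-1]) {
      m <- match(byf[[i]]$id, byf[[i - 1L]]$id)
      ok <- !is.na(m)
      v <- (byf[[i]]$x[ok] - byf[[i - 1L]]$x[m[ok]]) * rate
      vals[i - 1L] <- vals[i - 1L] + s_eye * mean(v)
    }
  }
  tms <- sort(unique(seq$frames$time))[seq_along(vals)]
  ts_trace(tms, vals, label = "interocular velocity difference (deg/s)")
}
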