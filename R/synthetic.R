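#' Synthetic swallow scenario
#'
#' Parameter bundle for the synthetic swallow generator. Defaults emulate the
#' study conditions of the macaque swallowing dataset the pipeline targets:
#' 200 Hz capture, one 1 s swallow gape cycle, tongue base retraction (TBR)
#' between 0.40 s and 0.70 s, hyoid protraction 4.23 mm and elevation
#' 2.13 mm over TBR, midline posterior marker retractions 6.25 / 4.30 /
#' 4.08 mm (posterior surface, posterior deep, vallecula), a tongue-base
#' length increase of 3.61 mm, regional volume changes of +0.85 mL
#' (posterior oral tongue) and +0.65 mL (tongue base) at constant anterior
#' oral tongue volume, styloglossus shortening of 0.76 mm and palatoglossus
#' lengthening of 0.07 mm, and 0.07 mm marker noise (the static-specimen
#' precision scale).
#'
#' Every event-defining marker trajectory is smooth: retractions follow
#' cosine ramps, preceded by a small anterior drift peaking exactly at TBR
#' onset and followed by a small rebound after offset, with curvatures
#' matched on both sides of each extremum so event frames are well defined.
#'
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param frame_rate capture rate, Hz.
#' @param duration cycle length, s.
#' @param t_tbr length-2: TBR onset and offset times, s.
#' @param t_ip length-2: intercuspal (zero pitch velocity) plateau, s.
#' @param hyoid_excursion named c(protraction, elevation), mm over TBR.
#' @param retraction named c(posterior_surface, posterior_deep, vallecula):
#'   posterior X displacement magnitudes over TBR, mm.
#' @param tb_length_increase target tongue-base length increase, mm; fixes
#'   the posterolateral marker retraction at
#'   \code{retraction["vallecula"] - tb_length_increase}.
#' @param posterior_deep_elevation Y displacement of the posterior deep
#'   marker over TBR, mm.
#' @param volume_targets named c(pot, tb): regional volume increases, mL.
#' @param muscle_targets named c(styloglossus, palatoglossus): programmed
#'   length changes, mm (hyoglossus shortening follows the hyoid excursion
#'   magnitude by construction).
#' @param gape_open_deg jaw pitch at cycle start/end, degrees.
#' @param marker_noise_sd marker noise SD, mm (0 = noiseless).
#' @param emg_fs EMG sampling rate, Hz.
#' @param emg_noise_sd EMG baseline noise SD (normalized units).
#' @param emg_burst_amp EMG burst amplitude (normalized units).
#' @return object of class \code{swallow_scenario}.
#' @export
swallow_scenario <- function(seed = 1L,
                             frame_rate = 200,
                             duration = 1.0,
                             t_tbr = c(0.40, 0.70),
                             t_ip = c(0.30, 0.40),
                             hyoid_excursion = c(protraction = 4.23, elevation = 2.13),
                             retraction = c(posterior_surface = 6.25,
                                            posterior_deep = 4.30,
                                            vallecula = 4.08),
                             tb_length_increase = 3.61,
                             posterior_deep_elevation = 2.5,
                             volume_targets = c(pot = 0.85, tb = 0.65),
                             muscle_targets = c(styloglossus = -0.76,
                                                palatoglossus = 0.07),
                             gape_open_deg = 8,
                             marker_noise_sd = 0.07,
                             emg_fs = 2000,
                             emg_noise_sd = 0.1,
                             emg_burst_amp = 1.0) {
  stopifnot(!missing(seed) || is.numeric(seed),
            t_tbr[1] < t_tbr[2], t_tbr[2] <= duration,
            marker_noise_sd >= 0, emg_noise_sd >= 0)
  sc <- as.list(environment())
  sc$seed <- as.integer(seed)
  class(sc) <- "swallow_scenario"
  sc
}

#' @export
print.swallow_scenario <- function(x, ...) {
  cat(sprintf("swallow_scenario: %g s @ %g Hz, TBR %.2f-%.2f s, noise %.3g mm, seed %d\n",
              x$duration, x$frame_rate, x$t_tbr[1], x$t_tbr[2],
              x$marker_noise_sd, x$seed))
  invisible(x)
}

# smooth step: 0 -> 1 over u in [0, 1], zero slope at both ends
sstep <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2

# Event-marker X path: baseline x0, anterior drift of A*(t_pre/T)^2 peaking
# at t_on (curvature-matched), cosine retraction of amplitude A over
# [t_on, t_off], rebound of A*(t_reb/T)^2 after t_off (curvature-matched).
event_x_path <- function(t, x_on, A, t_on, t_off) {
  T_ <- t_off - t_on
  t_pre <- T_ / 2
  t_reb <- T_ / 2
  pre <- A * (t_pre / T_)^2
  reb <- A * (t_reb / T_)^2
  x0 <- x_on - pre
  x <- x0 + pre * sstep((t - (t_on - t_pre)) / t_pre)
  mid <- t > t_on
  x[mid] <- x_on - A * sstep((t[mid] - t_on) / T_)
  post <- t > t_off
  x[post] <- (x_on - A) + reb * sstep((t[post] - t_off) / t_reb)
  x
}

# plain ramp path over [t_on, t_off]
ramp_path <- function(t, v0, dv, t_on, t_off) v0 + dv * sstep((t - t_on) / (t_off - t_on))

# baseline tongue constellation (mm, cranial frame; +X anterior, +Y superior,
# +Z right). Chosen to match macaque tongue proportions: posterior coronal
# ring ~22 mm wide x 20 mm deep, middle ring ~20 x 17, tongue ~45 mm from
# middle ring to tip.
tongue_baseline <- function() {
  rbind(anterior          = c(55,  7,   0),
        lateral_right     = c(35,  2,  10),
        lateral_left      = c(35,  2, -10),
        middle_surface    = c(35,  9,   0),
        middle_deep       = c(35, -8,   0),
        posterior_surface = c(18, 10,   0),
        posterior_right   = c(18,  2,  11),
        posterior_left    = c(18,  2, -11),
        posterior_deep    = c(20,  0,   0),
        vallecula         = c(10,  2,   0))
}

hyoid_dorsal_baseline <- function() c(18, -10, 0)

#' Generate tongue marker paths meeting regional volume targets
#'
#' Builds per-frame tongue marker trajectories whose programmed displacement
#' targets (retractions, hyoid-coupled ring boundary, tongue-base length
#' increase) are met exactly, and whose regional volume changes over TBR
#' match the requested targets within 2 percent. Two free degrees of freedom
#' are solved against the forward volume model (the same
#' spline-ring/harmonic-surface/primitive evaluation the pipeline uses):
#' posterior surface elevation controls the posterior-oral-tongue change,
#' vallecular elevation the tongue-base change. The anterior tongue and
#' middle ring stay fixed, holding AOT volume constant.
#'
#' @param scenario a \code{swallow_scenario}.
#' @param n_ring_solve,density_solve forward-model resolution used inside
#'   the root search (coarser than the final evaluation for speed).
#' @param max_iter root-search iteration cap per degree of freedom.
#' @return list with \code{paths} (frames x markers x 3 array of tongue
#'   marker positions), \code{hyoid_dorsal} (frames x 3),
#'   \code{solved} (named dy values), \code{achieved} (named volume deltas,
#'   mL, at the final evaluation resolution), \code{t} (frame times).
#' @export
generate_tongue_deformation <- function(scenario,
                                        n_ring_solve = 150,
                                        density_solve = 2,
                                        max_iter = 50) {
  sc <- scenario
  fs <- sc$frame_rate
  t <- seq(0, sc$duration - 1 / fs, by = 1 / fs)
  t_on <- sc$t_tbr[1]; t_off <- sc$t_tbr[2]
  base <- tongue_baseline()
  hyd0 <- hyoid_dorsal_baseline()
  hx <- sc$hyoid_excursion[["protraction"]]
  hy <- sc$hyoid_excursion[["elevation"]]
  lat_retr <- sc$retraction[["vallecula"]] - sc$tb_length_increase
  if (lat_retr < 0)
    stop("infeasible geometry: tb_length_increase exceeds vallecular retraction")

  # offset-frame control points given the two free elevations
  controls_at <- function(phase, dy_ps, dy_v) {
    # phase: 0 at onset, 1 at offset
    b <- base
    shift <- function(nm, dx = 0, dy = 0, dz = 0)
      b[nm, ] <<- b[nm, ] + phase * c(dx, dy, dz)
    shift("posterior_surface", dx = -sc$retraction[["posterior_surface"]], dy = dy_ps)
    shift("posterior_deep", dx = -sc$retraction[["posterior_deep"]],
          dy = sc$posterior_deep_elevation)
    shift("vallecula", dx = -sc$retraction[["vallecula"]], dy = dy_v)
    shift("posterior_right", dx = -lat_retr)
    shift("posterior_left", dx = -lat_retr)
    hyd <- hyd0 + phase * c(hx, hy, 0)
    list(markers = b, hyoid_dorsal = hyd)
  }

  vols_of <- function(cp, n_ring, density) {
    b <- cp$markers
    ring_m <- fit_coronal_ring(b[c("middle_deep", "lateral_left",
                                   "middle_surface", "lateral_right"), ])
    ring_p <- fit_coronal_ring(rbind(cp$hyoid_dorsal,
                                     b["posterior_left", ],
                                     b["posterior_surface", ],
                                     b["posterior_right", ]))
    rs <- resample_matched_rings(ring_m, ring_p, n = n_ring)
    sm <- fill_harmonic_surface(coronal_ring(rs$middle), density = density)
    sp <- fill_harmonic_surface(coronal_ring(rs$posterior), density = density)
    pr <- build_primitives(sm, sp, b["anterior", ], b["vallecula", ])
    c(aot = signed_mesh_volume(pr$aot) / 1000,
      pot = signed_mesh_volume(pr$pot) / 1000,
      tb = signed_mesh_volume(pr$tb) / 1000)
  }

  v_on <- vols_of(controls_at(0, 0, 0), n_ring_solve, density_solve)
  solve_dof <- function(f, interval) {
    # accept an endpoint that already meets the target (e.g. all-zero targets)
    lo <- f(interval[1])
    if (abs(lo) < 1e-4) return(interval[1])
    hi <- f(interval[2])
    if (lo * hi > 0)
      stop("volume-target scale search failed: no sign change over ",
           interval[1], "..", interval[2])
    stats::uniroot(f, interval, f.lower = lo, f.upper = hi,
                   tol = 1e-3, maxiter = max_iter)$root
  }
  static <- all(c(sc$retraction, sc$hyoid_excursion, sc$volume_targets,
                  sc$posterior_deep_elevation) == 0)
  if (static) {
    dy_ps <- dy_v <- 0                       # all-zero targets: no deformation
  } else {
    f_pot <- function(dy_ps)
      vols_of(controls_at(1, dy_ps, 0), n_ring_solve, density_solve)[["pot"]] -
        v_on[["pot"]] - sc$volume_targets[["pot"]]
    dy_ps <- solve_dof(f_pot, c(-8, 16))
    f_tb <- function(dy_v)
      vols_of(controls_at(1, dy_ps, dy_v), n_ring_solve, density_solve)[["tb"]] -
        v_on[["tb"]] - sc$volume_targets[["tb"]]
    dy_v <- solve_dof(f_tb, c(-8, 16))
  }

  # final evaluation at pipeline resolution
  v_on_f <- vols_of(controls_at(0, 0, 0), 300, 1)
  v_off_f <- vols_of(controls_at(1, dy_ps, dy_v), 300, 1)
  achieved <- v_off_f - v_on_f

  # per-frame paths
  nms <- rownames(base)
  paths <- array(NA_real_, c(length(t), length(nms), 3),
                 dimnames = list(NULL, nms, c("X", "Y", "Z")))
  retr_x <- c(posterior_surface = sc$retraction[["posterior_surface"]],
              posterior_deep = sc$retraction[["posterior_deep"]],
              vallecula = sc$retraction[["vallecula"]],
              posterior_right = lat_retr, posterior_left = lat_retr)
  elev_y <- c(posterior_surface = dy_ps,
              posterior_deep = sc$posterior_deep_elevation,
              vallecula = dy_v, posterior_right = 0, posterior_left = 0)
  for (nm in nms) {
    if (nm %in% names(retr_x)) {
      paths[, nm, 1] <- event_x_path(t, base[nm, 1], retr_x[[nm]], t_on, t_off)
      paths[, nm, 2] <- ramp_path(t, base[nm, 2], elev_y[[nm]], t_on, t_off)
      paths[, nm, 3] <- base[nm, 3]
    } else {
      for (k in 1:3) paths[, nm, k] <- base[nm, k]
    }
  }
  hyoid_dorsal <- cbind(ramp_path(t, hyd0[1], hx, t_on, t_off),
                        ramp_path(t, hyd0[2], hy, t_on, t_off),
                        rep(hyd0[3], length(t)))
  list(paths = paths, hyoid_dorsal = hyoid_dorsal,
       solved = c(posterior_surface_elevation = dy_ps,
                  vallecula_elevation = dy_v),
       achieved = achieved, t = t)
}

# bone-fixed marker clusters (mm)
bone_clusters <- function() {
  list(
    cranium = rbind(cran1 = c(0, 20, 0), cran2 = c(10, 25, 8),
                    cran3 = c(10, 25, -8), cran4 = c(22, 18, 0)),
    mandible = rbind(mand1 = c(45, -10, 0), mand2 = c(35, -12, 6),
                     mand3 = c(35, -12, -6), mand4 = c(15, -6, 10)),
    hyoid = rbind(hyo1 = c(20, -12, 4), hyo2 = c(20, -12, -4),
                  hyo3 = c(16, -15, 0), hyo4 = c(22, -16, 0))
  )
}

# Jaw pitch trace (degrees, opening positive): fast close -> intercuspal
# plateau (pitch 0) -> slow open -> fast open. The close ends and the open
# begins at full velocity (tooth contact stops the jaw abruptly and release
# is sudden), so the zero-velocity plateau has sharp edges.
gape_trace <- function(t, t_ip, open_deg, duration) {
  th <- numeric(length(t))
  pre <- t < t_ip[1]
  th[pre] <- open_deg * cos(pi / 2 * t[pre] / t_ip[1])
  t3 <- 0.8 * duration
  slow <- t > t_ip[2] & t <= t3
  th[slow] <- (open_deg * 0.35) * sin(pi / 2 * (t[slow] - t_ip[2]) / (t3 - t_ip[2]))
  fast <- t > t3
  th[fast] <- open_deg * 0.35 +
    (open_deg - open_deg * 0.35) * sstep((t[fast] - t3) / (duration - t3))
  th
}

# pose of the mandible for pitch theta (deg): rotation -theta about +Z
# through the condylar pivot
mandible_pose_at <- function(theta_deg, pivot = c(2, 2, 0)) {
  a <- -theta_deg * pi / 180
  R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  list(R = R, t = as.numeric(pivot - R %*% pivot))
}

# reference landmark clouds bounding the oral cavity (cranial frame for the
# palate/teeth; bone-fixed for mandible and hyoid)
oral_reference_clouds <- function(density = 1.35) {
  gx <- function(n) seq(12, 52, length.out = round(n * density))
  gz <- function(n) seq(-11, 11, length.out = round(n * density))
  palate <- as.matrix(expand.grid(X = gx(46), Y = NA, Z = gz(26)))
  palate[, 2] <- 10 + 1.5 * cos(pi * palate[, 3] / 24)
  teeth <- do.call(rbind, lapply(c(-12, 12), function(z) {
    g <- as.matrix(expand.grid(X = gx(42), Y = seq(2, 10, length.out = round(9 * density))))
    cbind(g[, 1], g[, 2], z)
  }))
  # mandible lingual surface + symphysis (bone-fixed = cranial frame at pitch 0)
  mand <- do.call(rbind, lapply(c(-11.5, 11.5), function(z) {
    g <- as.matrix(expand.grid(X = gx(42), Y = seq(-9, 1, length.out = round(11 * density))))
    cbind(g[, 1], g[, 2], z)
  }))
  sym <- as.matrix(expand.grid(Y = seq(-9, 1, length.out = round(11 * density)),
                               Z = seq(-10, 10, length.out = round(18 * density))))
  sym <- cbind(50 - 0.02 * sym[, 2]^2, sym[, 1], sym[, 2])
  hyoid <- as.matrix(expand.grid(Y = seq(-18, -8, length.out = round(12 * density)),
                                 Z = seq(-6, 6, length.out = round(14 * density))))
  hyoid <- cbind(19 - 0.05 * hyoid[, 2]^2, hyoid[, 1], hyoid[, 2])
  list(cranial = rbind(palate, teeth), mandible = rbind(mand, sym), hyoid = hyoid)
}

# amplitude-modulated EMG channel: white noise baseline plus bursts of
# amplitude-scaled white noise with 20 ms cosine edges
emg_channel_signal <- function(tt, bursts, noise_sd, amp) {
  env <- numeric(length(tt))
  for (b in bursts) {
    edge <- 0.02
    u <- rep(0, length(tt))
    u[tt >= b[1] & tt < b[1] + edge] <- sstep((tt[tt >= b[1] & tt < b[1] + edge] - b[1]) / edge)
    u[tt >= b[1] + edge & tt <= b[2] - edge] <- 1
    sel <- tt > b[2] - edge & tt <= b[2]
    u[sel] <- 1 - sstep((tt[sel] - (b[2] - edge)) / edge)
    env <- pmax(env, u)
  }
  stats::rnorm(length(tt), 0, noise_sd) + amp * env * stats::rnorm(length(tt))
}

#' Generate a full synthetic swallow dataset with ground truth
#'
#' Produces every input the analysis pipeline consumes — tongue and muscle
#' marker trajectories, bone-fixed marker clusters and their moving
#' observations, oral-cavity boundary reference clouds, multichannel raw EMG
#' — together with a ground-truth record of every programmed quantity
#' (event frames, displacement and volume deltas, muscle length changes,
#' burst windows). Deterministic given the scenario seed.
#'
#' Muscle attachments: styloglossus and palatoglossus insertion markers move
#' along their origin lines so the programmed length changes are met
#' exactly; the hyoglossus insertion sits on the hyoid excursion line so its
#' shortening equals the hyoid excursion magnitude.
#'
#' @param scenario a \code{swallow_scenario}.
#' @param out_dir optional directory; when given, writes marker/bone/EMG CSV
#'   tables and a ground-truth JSON there.
#' @return list with \code{markers} (tongue + muscle-insertion
#'   \code{marker_set}, noisy per scenario), \code{bones} (list of observed
#'   bone-cluster \code{marker_set}s), \code{bone_refs} (bone-fixed
#'   clusters), \code{hyoid_dorsal} (clean frames x 3), \code{gape_deg}
#'   (programmed pitch), \code{emg} (list of channels: \code{raw},
#'   \code{fs}, \code{bursts}), \code{clouds} (oral reference clouds),
#'   \code{raphe} (function(frame) -> 2 x 3 endpoints), \code{truth},
#'   \code{scenario}.
#' @export
generate_scenario <- function(scenario, out_dir = NULL) {
  sc <- scenario
  set.seed(sc$seed)
  fs <- sc$frame_rate
  t <- seq(0, sc$duration - 1 / fs, by = 1 / fs)
  nfr <- length(t)
  t_on <- sc$t_tbr[1]; t_off <- sc$t_tbr[2]
  on_f <- which.min(abs(t - t_on)); off_f <- which.min(abs(t - t_off))

  def <- generate_tongue_deformation(sc)

  # --- muscle attachment constructions -----------------------------------
  o_sg <- c(12, 10, 12)                       # styloid region (cranial, fixed)
  i_sg0 <- c(30, 4, 9)
  u_sg <- (o_sg - i_sg0) / sqrt(sum((o_sg - i_sg0)^2))
  o_pg <- c(30, 12, 8)                        # palatal origin (fixed)
  i_pg0 <- c(24, 5, 9)
  u_pg <- (o_pg - i_pg0) / sqrt(sum((o_pg - i_pg0)^2))
  hx <- sc$hyoid_excursion[["protraction"]]; hyv <- sc$hyoid_excursion[["elevation"]]
  h_disp <- c(hx, hyv, 0)
  o_hg0 <- c(20, -12, 5)                      # hyoglossus origin on hyoid body
  i_hg <- o_hg0 + 45 * h_disp / sqrt(sum(h_disp^2))  # insertion on excursion line
  ramp <- sstep((t - t_on) / (t_off - t_on))
  mus <- array(NA_real_, c(nfr, 3, 3),
               dimnames = list(NULL, c("styloglossus_ins", "palatoglossus_ins",
                                       "hyoglossus_ins"), c("X", "Y", "Z")))
  for (k in 1:3) {
    mus[, 1, k] <- i_sg0[k] - u_sg[k] * sc$muscle_targets[["styloglossus"]] * ramp
    mus[, 2, k] <- i_pg0[k] - u_pg[k] * sc$muscle_targets[["palatoglossus"]] * ramp
    mus[, 3, k] <- i_hg[k]
  }

  # --- bones --------------------------------------------------------------
  refs <- bone_clusters()
  gape <- gape_trace(t, sc$t_ip, sc$gape_open_deg, sc$duration)
  hy_path <- cbind(ramp * hx, ramp * hyv, 0)
  obs <- list()
  obs$cranium <- array(rep(t(refs$cranium), each = nfr), c(nfr, 3, nrow(refs$cranium)))
  mand <- array(NA_real_, c(nfr, nrow(refs$mandible), 3))
  hyo <- array(NA_real_, c(nfr, nrow(refs$hyoid), 3))
  for (f in seq_len(nfr)) {
    mp <- mandible_pose_at(gape[f])
    mand[f, , ] <- sweep(refs$mandible %*% t(mp$R), 2, mp$t, `+`)
    hyo[f, , ] <- sweep(refs$hyoid, 2, hy_path[f, ], `+`)
  }
  cran <- array(rep(refs$cranium, each = nfr), c(nfr, nrow(refs$cranium), 3))

  # --- marker noise -------------------------------------------------------
  tongue <- def$paths
  noisy <- function(a) {
    if (sc$marker_noise_sd <= 0) return(a)
    a + array(stats::rnorm(length(a), 0, sc$marker_noise_sd), dim = dim(a))
  }
  tongue_n <- noisy(tongue)
  mus_n <- noisy(mus)
  cran_n <- noisy(cran); mand_n <- noisy(mand); hyo_n <- noisy(hyo)

  nt <- dim(tongue)[2]
  all_tongue <- array(NA_real_, c(nfr, nt + 3, 3))
  all_tongue[, seq_len(nt), ] <- tongue_n
  all_tongue[, nt + 1:3, ] <- mus_n
  markers <- marker_set(all_tongue,
                        c(dimnames(tongue)[[2]], dimnames(mus)[[2]]), fs)
  bones <- list(cranium = marker_set(cran_n, rownames(refs$cranium), fs),
                mandible = marker_set(mand_n, rownames(refs$mandible), fs),
                hyoid = marker_set(hyo_n, rownames(refs$hyoid), fs))

  # --- EMG ----------------------------------------------------------------
  tt <- seq(0, sc$duration - 1 / sc$emg_fs, by = 1 / sc$emg_fs)
  burst_schedule <- list(
    geniohyoid = list(c(t_on, t_off)),
    mylohyoid = list(c(t_on - 0.15, t_on + 0.10)),
    anterior_digastric = list(c(t_on - 0.15, t_on - 0.02)),
    genioglossus = list(c(t_on - 0.20, t_on - 0.05)),
    styloglossus = list(c(t_on, t_off))
  )
  emg <- lapply(burst_schedule, function(b)
    list(raw = emg_channel_signal(tt, b, sc$emg_noise_sd, sc$emg_burst_amp),
         fs = sc$emg_fs, bursts = b))

  # --- oral cavity boundary -----------------------------------------------
  clouds <- oral_reference_clouds()
  raphe <- function(f) rbind(c(19, -18, 0) + hy_path[f, ],   # inferior hyoid pole
                             c(49, -8, 0))                   # symphysis (near-static)

  # --- ground truth -------------------------------------------------------
  lat_retr <- sc$retraction[["vallecula"]] - sc$tb_length_increase
  mlen <- function(o, ins) sqrt(colSums((t(ins) - o)^2))
  sg_len <- mlen(o_sg, mus[, 1, ]); pg_len <- mlen(o_pg, mus[, 2, ])
  hg_len <- sqrt(rowSums((matrix(i_hg, nfr, 3, byrow = TRUE) -
                          (matrix(o_hg0, nfr, 3, byrow = TRUE) + hy_path))^2))
  truth <- list(
    seed = sc$seed,
    onset_frame = on_f, offset_frame = off_f,
    ip_window_s = sc$t_ip,
    gape_deg = gape,
    hyoid = c(protraction = hx, elevation = hyv),
    retraction = c(sc$retraction, posterior_lateral = lat_retr),
    tb_length_increase = sc$tb_length_increase,
    volume_deltas_ml = def$achieved,
    solved_elevations = def$solved,
    muscle_deltas_mm = c(styloglossus = unname(sg_len[off_f] - sg_len[on_f]),
                         palatoglossus = unname(pg_len[off_f] - pg_len[on_f]),
                         hyoglossus = unname(hg_len[off_f] - hg_len[on_f])),
    emg_bursts_s = burst_schedule
  )

  out <- list(markers = markers, bones = bones, bone_refs = refs,
              hyoid_dorsal = def$hyoid_dorsal, gape_deg = gape,
              emg = emg, clouds = clouds, raphe = raphe,
              truth = truth, scenario = sc)
  if (!is.null(out_dir)) write_scenario(out, out_dir)
  out
}

# write a generated scenario to disk: CSV tables + ground-truth JSON
write_scenario <- function(gen, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_table(gen$markers, file.path(out_dir, "tongue_markers.csv"))
  for (nm in names(gen$bones))
    write_marker_table(gen$bones[[nm]], file.path(out_dir, paste0(nm, "_markers.csv")))
  hd <- data.frame(frame = seq_len(nrow(gen$hyoid_dorsal)),
                   X = gen$hyoid_dorsal[, 1], Y = gen$hyoid_dorsal[, 2],
                   Z = gen$hyoid_dorsal[, 3])
  utils::write.csv(hd, file.path(out_dir, "hyoid_dorsal.csv"), row.names = FALSE)
  for (nm in names(gen$emg)) {
    utils::write.csv(data.frame(signal = gen$emg[[nm]]$raw),
                     file.path(out_dir, paste0("emg_", nm, ".csv")),
                     row.names = FALSE)
  }
  tr <- gen$truth
  tr$gape_deg <- NULL                          # keep the JSON small
  # named atomic vectors as JSON objects, not bare arrays
  tr <- lapply(tr, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(tr, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Synthetic per-cycle summary table with programmed correlation
#'
#' Draws per-cycle hyoid protraction and posterior-surface retraction values
#' from a bivariate normal with the requested Pearson correlation, plus
#' independent columns for the other kinematic variables, emulating a pooled
#' table of swallow cycles.
#'
#' @param n_cycles number of swallow cycles (default 85, the intercalated
#'   swallow count the pipeline's statistics layer targets).
#' @param r programmed correlation between hyoid X and posterior surface X
#'   (default -0.84).
#' @param seed integer seed.
#' @return data.frame with columns \code{hyoid_x}, \code{post_surf_x},
#'   \code{post_deep_x}, \code{vallecula_x}, \code{styloglossus_delta}.
#' @export
generate_cycle_summaries <- function(n_cycles = 85, r = -0.84, seed = 1L) {
  set.seed(seed)
  z1 <- stats::rnorm(n_cycles); z2 <- stats::rnorm(n_cycles)
  hyoid_x <- 4.23 + 1.51 * z1
  post_surf_x <- -6.25 + 1.88 * (r * z1 + sqrt(1 - r^2) * z2)
  data.frame(
    hyoid_x = hyoid_x,
    post_surf_x = post_surf_x,
    post_deep_x = -4.30 + 0.89 * stats::rnorm(n_cycles),
    vallecula_x = -4.08 + 1.57 * stats::rnorm(n_cycles),
    styloglossus_delta = -0.76 + 1.32 * stats::rnorm(n_cycles)
  )
}

#' Synthetic static precision recording
#'
#' Static marker constellation plus isotropic Gaussian noise, emulating the
#' frozen-specimen precision experiment used to derive pooled SDs and
#' zero-velocity bands.
#'
#' @param n_frames recording length, frames.
#' @param noise_sd marker noise SD, mm.
#' @param frame_rate Hz.
#' @param seed integer seed.
#' @return a \code{marker_set} of the static tongue constellation.
#' @export
generate_precision_recording <- function(n_frames = 500, noise_sd = 0.07,
                                         frame_rate = 200, seed = 1L) {
  set.seed(seed)
  base <- tongue_baseline()
  a <- array(rep(base, each = n_frames), c(n_frames, nrow(base), 3)) +
    array(stats::rnorm(n_frames * nrow(base) * 3, 0, noise_sd),
          c(n_frames, nrow(base), 3))
  marker_set(a, rownames(base), frame_rate)
}
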