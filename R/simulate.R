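#' Field geometry for the simulator
#'
#' Defaults emulate a 10x high-content acquisition at desk scale: 512x512
#' 16-bit fields, ~0.65 um pixels, nuclei with equivalent diameters of
#' roughly 15-25 px placed without overlap.
#'
#' @param width,height Field size in pixels.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param margin Minimum distance (px) between a nucleus centre and the
#'   field border, in addition to its major semi-axis, so no rendered
#'   nucleus touches the border.
#' @param min_gap Minimum gap (px) between the footprints of two nuclei.
#' @param max_place_tries Rejection-sampling attempts per nucleus before a
#'   placement error is raised.
#' @return An object of class `field_geometry`.
#' @export
field_geometry <- function(width = 512, height = 512, pixel_size_um = 0.65,
                           margin = 6, min_gap = 3, max_place_tries = 400) {
  stopifnot(width >= 32, height >= 32, pixel_size_um > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size_um = pixel_size_um, margin = margin,
                 min_gap = min_gap, max_place_tries = max_place_tries),
            class = "field_geometry")
}

#' Rendering parameters for simulated nuclei
#'
#' The DNA channel encodes DNA content: the integrated intensity of a
#' nucleus is proportional to its content times a lognormal staining
#' factor, and its area to content^(2/3) (volume proportional to content,
#' projected area to volume^(2/3)) times a lognormal factor. Chromatin
#' texture is band-passed Gaussian noise whose correlation length grows
#' from G1 to S/G2/M, so texture features carry phase information.
#' Fucci channel means are drawn with at least a 25% margin on the correct
#' side of the gating thresholds; apoptotic nuclei are rendered as 4-6
#' bright fragments over a dim body, giving DNA-channel CVs well above the
#' 70% exclusion threshold.
#'
#' @param base_area_px Mean nucleus area (px) at DNA content 2 (G1).
#' @param area_sd_log Lognormal sigma of the area factor.
#' @param base_total_intensity Mean integrated DNA intensity (counts) at
#'   content 2.
#' @param intensity_sd_log Lognormal sigma of the staining factor.
#' @param texture_amp Amplitude of the multiplicative chromatin texture.
#' @param texture_sigma Named vector of texture correlation scales (px) per
#'   phase.
#' @param edge_soft Fraction of the radius over which intensity falls to 0
#'   at the nucleus edge.
#' @param axis_ratio_max Maximum semi-axis ratio of the elliptical outline.
#' @param fucci_margin_above,fucci_margin_below Closest allowed ratio of a
#'   drawn Fucci mean to its threshold (above / below the gate).
#' @param fucci_spread Lognormal spread of Fucci means away from the gate.
#' @param frag_bright Peak intensity (counts) of apoptotic fragments.
#' @param frag_body_frac Dim-body intensity as a fraction of `frag_bright`.
#' @return An object of class `render_params`.
#' @export
render_params <- function(base_area_px = 210, area_sd_log = 0.08,
                          base_total_intensity = 6e5, intensity_sd_log = 0.10,
                          texture_amp = 0.25,
                          texture_sigma = c(G1 = 1.2, earlyS = 1.5,
                                            SG2M = 2.0, DN = 1.2,
                                            apoptotic = 1.2),
                          edge_soft = 0.15, axis_ratio_max = 1.35,
                          fucci_margin_above = 1.25,
                          fucci_margin_below = 0.72,
                          fucci_spread = 0.35,
                          frag_bright = 9000, frag_body_frac = 0.12) {
  stopifnot(base_area_px > 0, base_total_intensity > 0,
            fucci_margin_above >= 1.2, fucci_margin_below <= 0.8)
  structure(as.list(environment()), class = "render_params")
}

#' Noise model for simulated fields
#'
#' Per channel: a smooth parabolic background dome is added, Poisson shot
#' noise is applied to the expected photon counts, and Gaussian read noise
#' is added before clipping to the 16-bit range. `label_noise_rate` is the
#' probability that a nucleus's drawn Fucci intensity crosses a gating
#' threshold (split evenly between the two channels), i.e. the rate of
#' ground-truth label noise.
#'
#' @param profile `"default"` or `"none"`; `"none"` zeroes every noise
#'   source (used for noiseless oracle checks).
#' @param poisson Apply Poisson shot noise.
#' @param read_sd Gaussian read noise SD (counts).
#' @param background_amp DNA-channel background dome amplitude (counts).
#' @param fucci_background_amp Fucci-channel dome amplitude (counts).
#' @param label_noise_rate See above; default 2% of nuclei.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(profile = c("default", "none"), poisson = NULL,
                         read_sd = NULL, background_amp = NULL,
                         fucci_background_amp = NULL,
                         label_noise_rate = NULL) {
  profile <- match.arg(profile)
  d <- if (profile == "none") {
    list(poisson = FALSE, read_sd = 0, background_amp = 0,
         fucci_background_amp = 0, label_noise_rate = 0)
  } else {
    list(poisson = TRUE, read_sd = 3, background_amp = 60,
         fucci_background_amp = 20, label_noise_rate = 0.02)
  }
  structure(list(poisson = poisson %||% d$poisson,
                 read_sd = read_sd %||% d$read_sd,
                 background_amp = background_amp %||% d$background_amp,
                 fucci_background_amp = fucci_background_amp %||%
                   d$fucci_background_amp,
                 label_noise_rate = label_noise_rate %||% d$label_noise_rate),
            class = "noise_params")
}

#' Draw a cell population for one condition
#'
#' Each cell is apoptotic with probability `apoptotic_frac`, otherwise its
#' phase is drawn from the preset's `phase_probs`. DNA content is 2 genome
#' equivalents in G1, uniform in \[2, 2.5\] in early S, uniform in
#' \[2.5, 4\] in S/G2/M, and uniform in \[2, 4\] for double-negative and
#' apoptotic cells (whose content the gates do not constrain).
#'
#' @param preset A [condition_preset()].
#' @param n_cells Number of cells to draw (>= 0).
#' @param seed Integer seed; draws are i.i.d. and reproducible.
#' @return A data.frame with columns `phase` (character, one of G1,
#'   earlyS, SG2M, DN, apoptotic) and `dna_content`.
#' @examples
#' pop <- sample_population(condition_presets("HeLa")$control, 10, seed = 1)
#' @export
sample_population <- function(preset, n_cells, seed = 1) {
  stopifnot(inherits(preset, "condition_preset"), n_cells >= 0)
  if (n_cells == 0) {
    return(data.frame(phase = character(0), dna_content = numeric(0)))
  }
  with_seed(seed, {
    apo <- runif(n_cells) < preset$apoptotic_frac
    phase <- sample(phase_levels(), n_cells, replace = TRUE,
                    prob = preset$phase_probs)
    phase[apo] <- "apoptotic"
    lo <- c(G1 = 2, earlyS = 2, SG2M = 2.5, DN = 2, apoptotic = 2)
    hi <- c(G1 = 2, earlyS = 2.5, SG2M = 4, DN = 4, apoptotic = 4)
    dna <- runif(n_cells, lo[phase], hi[phase])
    data.frame(phase = phase, dna_content = dna)
  })
}

# Band-passed unit-variance noise field (difference of Gaussians of the
# same white-noise draw), used as multiplicative chromatin texture.
texture_field <- function(h, w, sigma) {
  n <- matrix(rnorm(h * w), h, w)
  bp <- as.matrix(EBImage::gblur(n, sigma = sigma)) -
    as.matrix(EBImage::gblur(n, sigma = 2 * sigma))
  s <- stats::sd(bp)
  if (s == 0) bp else bp / s
}

# Draw one Fucci channel mean relative to a threshold.
draw_fucci_level <- function(above, thr, rp, label_noise_rate) {
  flip <- runif(1) < label_noise_rate / 2
  if (xor(above, flip)) {
    if (flip) thr * runif(1, 1.02, 1.10)
    else thr * rp$fucci_margin_above * exp(abs(rnorm(1)) * rp$fucci_spread)
  } else {
    if (flip) thr * runif(1, 0.90, 0.98)
    else thr * rp$fucci_margin_below * exp(-abs(rnorm(1)) * rp$fucci_spread)
  }
}

#' Render one multi-channel field from a cell population
#'
#' Places the nuclei without overlap and renders three channels: DNA stain
#' (textured ellipses whose integrated intensity and area scale with DNA
#' content; apoptotic cells as bright fragments over a dim body), and the
#' red and green Fucci reporters (uniform per-nucleus levels consistent
#' with the gating thresholds for the true phase). Background and noise
#' are then applied per [noise_params()] and pixels quantized to 16 bits.
#'
#' @param states data.frame from [sample_population()].
#' @param geometry A [field_geometry()].
#' @param render A [render_params()].
#' @param noise A [noise_params()].
#' @param gating A [fucci_gating_config()]; Fucci levels are drawn relative
#'   to its thresholds so that noiseless gating recovers the true phase.
#' @param seed Integer seed.
#' @param well_id Identifier stored with the field.
#' @return An object of class `image_field`: list with `pixels` (named
#'   list of `height x width` matrices: dna, red, green), `pixel_size_um`,
#'   `well_id`, `truth` (per-nucleus data.frame with phase, dna_content,
#'   0-based centroids, true Fucci levels) and `truth_labels` (integer
#'   matrix of disjoint ground-truth masks; 0 = background).
#' @export
render_field <- function(states, geometry = field_geometry(),
                         render = render_params(),
                         noise = noise_params(),
                         gating = fucci_gating_config("HeLa"),
                         seed = 1, well_id = "well") {
  stopifnot(inherits(geometry, "field_geometry"),
            inherits(render, "render_params"),
            inherits(noise, "noise_params"),
            inherits(gating, "fucci_gating_config"))
  h <- geometry$height; w <- geometry$width
  n <- nrow(states)
  with_seed(seed, {
    dna <- matrix(0, h, w); red <- matrix(0, h, w); grn <- matrix(0, h, w)
    labels <- matrix(0L, h, w)
    truth <- NULL
    if (n > 0) {
      rp <- render
      content <- states$dna_content
      area <- rp$base_area_px * (content / 2)^(2 / 3) *
        exp(rnorm(n, 0, rp$area_sd_log))
      total <- rp$base_total_intensity * (content / 2) *
        exp(rnorm(n, 0, rp$intensity_sd_log))
      ratio <- runif(n, 1, rp$axis_ratio_max)
      a <- sqrt(area / pi) * sqrt(ratio)   # major semi-axis
      b <- sqrt(area / pi) / sqrt(ratio)   # minor semi-axis
      theta <- runif(n, 0, pi)
      # non-overlap placement by rejection sampling
      cx <- numeric(n); cy <- numeric(n)
      for (i in seq_len(n)) {
        placed <- FALSE
        lo_x <- geometry$margin + a[i] + 1
        hi_x <- w - geometry$margin - a[i]
        lo_y <- geometry$margin + a[i] + 1
        hi_y <- h - geometry$margin - a[i]
        if (hi_x <= lo_x || hi_y <= lo_y) {
          stop("field too small for requested nucleus count", call. = FALSE)
        }
        for (try in seq_len(geometry$max_place_tries)) {
          px <- runif(1, lo_x, hi_x); py <- runif(1, lo_y, hi_y)
          if (i == 1) { ok <- TRUE } else {
            j <- seq_len(i - 1)
            ok <- all((px - cx[j])^2 + (py - cy[j])^2 >
                        (a[i] + a[j] + geometry$min_gap)^2)
          }
          if (ok) { cx[i] <- px; cy[i] <- py; placed <- TRUE; break }
        }
        if (!placed) {
          stop("field too small for requested nucleus count", call. = FALSE)
        }
      }
      # one texture field per distinct correlation scale
      sig_used <- unique(rp$texture_sigma[states$phase])
      tex <- lapply(sig_used, function(s) texture_field(h, w, s))
      names(tex) <- as.character(sig_used)
      red_true <- numeric(n); grn_true <- numeric(n)
      for (i in seq_len(n)) {
        r0 <- max(1L, floor(cy[i] - a[i] - 2)); r1 <- min(h, ceiling(cy[i] + a[i] + 2))
        c0 <- max(1L, floor(cx[i] - a[i] - 2)); c1 <- min(w, ceiling(cx[i] + a[i] + 2))
        rows <- r0:r1; cols <- c0:c1
        dx <- outer(rep(1, length(rows)), cols - cx[i])
        dy <- outer(rows - cy[i], rep(1, length(cols)))
        xr <- dx * cos(theta[i]) + dy * sin(theta[i])
        yr <- -dx * sin(theta[i]) + dy * cos(theta[i])
        q <- sqrt((xr / a[i])^2 + (yr / b[i])^2)
        inside <- q <= 1
        if (!any(inside)) next
        wgt <- clamp((1 - q) / render$edge_soft, 0, 1)
        ph <- states$phase[i]
        if (ph == "apoptotic") {
          patch <- wgt * rp$frag_body_frac * rp$frag_bright
          k <- sample(4:6, 1)
          fx <- runif(k, -0.6, 0.6) * a[i]; fy <- runif(k, -0.6, 0.6) * b[i]
          fr <- runif(k, 2.2, 3.2)
          for (f in seq_len(k)) {
            d2 <- (xr - fx[f])^2 + (yr - fy[f])^2
            patch <- patch + inside * rp$frag_bright * exp(-d2 / (2 * (fr[f] / 2)^2))
          }
        } else {
          sig <- rp$texture_sigma[[ph]]
          tx <- tex[[as.character(sig)]][rows, cols, drop = FALSE]
          patch <- wgt * pmax(1 + rp$texture_amp * tx, 0.15)
          s <- sum(patch)
          if (s > 0) patch <- patch * (total[i] / s)
        }
        dna[rows, cols] <- dna[rows, cols] + patch
        lbl <- labels[rows, cols]
        lbl[inside] <- i
        labels[rows, cols] <- lbl
        # Fucci levels per true phase (apoptotic rendered double negative)
        red_on <- ph %in% c("G1", "earlyS")
        grn_on <- ph %in% c("earlyS", "SG2M")
        red_true[i] <- draw_fucci_level(red_on, gating$red_threshold, rp,
                                        noise$label_noise_rate)
        grn_true[i] <- draw_fucci_level(grn_on, gating$green_threshold, rp,
                                        noise$label_noise_rate)
        red[rows, cols] <- red[rows, cols] + inside * red_true[i]
        grn[rows, cols] <- grn[rows, cols] + inside * grn_true[i]
      }
      truth <- data.frame(
        nucleus_id = seq_len(n), phase = states$phase,
        dna_content = states$dna_content,
        centroid_x = cx - 1, centroid_y = cy - 1,
        red_mean_true = red_true, green_mean_true = grn_true
      )
    } else {
      truth <- data.frame(nucleus_id = integer(0), phase = character(0),
                          dna_content = numeric(0), centroid_x = numeric(0),
                          centroid_y = numeric(0), red_mean_true = numeric(0),
                          green_mean_true = numeric(0))
    }
    # smooth parabolic background dome + shot/read noise, per channel
    dome <- {
      bx <- runif(1, 0.3, 0.7) * w; by <- runif(1, 0.3, 0.7) * h
      dd <- outer((seq_len(h) - by)^2, (seq_len(w) - bx)^2, `+`)
      1 - dd / max(w, h)^2
    }
    finish <- function(ch, amp) {
      ch <- ch + amp * dome
      if (noise$poisson) {
        ch[] <- rpois(length(ch), lambda = pmax(ch, 0))
      }
      if (noise$read_sd > 0) {
        ch <- ch + rnorm(length(ch), 0, noise$read_sd)
      }
      matrix(clamp(round(ch), 0, 65535), nrow(ch), ncol(ch))
    }
    structure(list(
      pixels = list(dna = finish(dna, noise$background_amp),
                    red = finish(red, noise$fucci_background_amp),
                    green = finish(grn, noise$fucci_background_amp)),
      pixel_size_um = geometry$pixel_size_um,
      well_id = well_id, truth = truth, truth_labels = labels
    ), class = "image_field")
  })
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> %s: %d x %d px, %d nuclei, %.2f um/px\n",
              x$well_id, nrow(x$pixels$dna), ncol(x$pixels$dna),
              nrow(x$truth), x$pixel_size_um))
  invisible(x)
}

#' Simulate all fields of a plate experiment in memory
#'
#' @param presets Named list of [condition_preset()] objects.
#' @param fields_per_condition Number of fields imaged per condition.
#' @param seed Master seed; each field gets a derived seed.
#' @param nuclei_per_field Mean number of cells per field (Poisson).
#' @param geometry,render,noise,gating Passed to [render_field()]; `gating`
#'   defaults to the config of each preset's cell line.
#' @return List of `image_field` objects; each carries a `meta` element
#'   (field_id, well, cell_line, drug, concentration_M).
#' @export
simulate_fields <- function(presets, fields_per_condition = 2, seed = 1,
                            nuclei_per_field = 100,
                            geometry = field_geometry(),
                            render = render_params(),
                            noise = noise_params(),
                            gating = NULL) {
  stopifnot(length(presets) >= 1)
  fields <- list()
  fid <- 0L
  for (ci in seq_along(presets)) {
    preset <- presets[[ci]]
    g <- gating %||% fucci_gating_config(preset$cell_line)
    for (fi in seq_len(fields_per_condition)) {
      fid <- fid + 1L
      fseed <- derive_seed(seed, sprintf("field_%d_%d", ci, fi))
      ncell <- with_seed(derive_seed(fseed, "count"),
                         rpois(1, nuclei_per_field))
      states <- sample_population(preset, ncell,
                                  seed = derive_seed(fseed, "pop"))
      well <- sprintf("%s_%02d", names(presets)[ci] %||% preset$drug, fi)
      fld <- render_field(states, geometry = geometry, render = render,
                          noise = noise, gating = g,
                          seed = derive_seed(fseed, "render"),
                          well_id = well)
      fld$meta <- data.frame(
        field_id = sprintf("f%04d", fid), well = well,
        cell_line = preset$cell_line, drug = preset$drug,
        concentration_M = preset$concentration
      )
      fields[[fid]] <- fld
    }
  }
  fields
}

#' Simulate a plate experiment to disk
#'
#' Writes one multi-page 16-bit TIFF per field (page order: DNA, red,
#' green) with a JSON sidecar (channel roles, pixel size), plus
#' `metadata.csv` (field_id, well, cell_line, drug, concentration_M) and
#' `truth.csv` (per-nucleus ground truth with 0-based centroids,
#' x = column). Output is reproducible per seed.
#'
#' @inheritParams simulate_fields
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of `image_field` objects written.
#' @export
simulate_plate <- function(presets, fields_per_condition = 2,
                           out_dir = "plate", seed = 1, ...) {
  fields <- simulate_fields(presets, fields_per_condition, seed, ...)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  meta <- do.call(rbind, lapply(fields, `[[`, "meta"))
  truth <- do.call(rbind, lapply(fields, function(f) {
    if (nrow(f$truth) == 0) return(NULL)
    cbind(field_id = f$meta$field_id, f$truth)
  }))
  for (f in fields) {
    base <- file.path(out_dir, f$meta$field_id)
    tiff::writeTIFF(lapply(f$pixels, function(m) m / 65535),
                    paste0(base, ".tiff"), bits.per.sample = 16,
                    compression = "none")
    jsonlite::write_json(
      list(channels = c("dna", "red", "green"),
           pixel_size_um = f$pixel_size_um, well_id = f$well_id),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(fields)
}

#' Read one simulated field back from disk
#'
#' @param tiff_path Path to a field TIFF written by [simulate_plate()].
#' @return An `image_field` (without ground truth, which lives in
#'   `truth.csv`).
#' @export
read_field <- function(tiff_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  side <- jsonlite::read_json(sub("\\.tiff?$", ".json", tiff_path),
                              simplifyVector = TRUE)
  px <- lapply(pages, function(p) round(p * 65535))
  names(px) <- side$channels
  structure(list(pixels = px, pixel_size_um = side$pixel_size_um,
                 well_id = side$well_id, truth = NULL, truth_labels = NULL),
            class = "image_field")
}
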