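#' Plant ground-truth synapses for a synthetic organ-of-Corti field
#'
#' Lays out a row of inner hair cells (IHCs) and plants paired presynaptic
#' (ribbon, CtBP2-like) and postsynaptic (receptor, GluA2-like) puncta plus
#' optional unpaired orphans. Puncta sit on a "basal ring" near the cell
#' footprint boundary — emulating the ring of ribbon synapses around the
#' basolateral pole of an IHC — which keeps nearest-neighbour spacing in the
#' projection plane realistic (~1.2-1.5 um for 16 synapses/cell) without
#' hand-placing coordinates. Paired puncta are separated by a synaptic-cleft
#' offset directed radially outward from the cell with a random axial tilt,
#' mimicking the receptor patch sitting just outside/below the ribbon.
#'
#' @param n_cells number of IHCs in the field (default 10).
#' @param pairs_per_cell integer constant, or a function `f(n_cells)`
#'   returning one count per cell (default 16).
#' @param orphan_rate per-channel probability that an extra unpaired punctum
#'   accompanies each planted pair; scalar or named vector
#'   `c(ribbon = , receptor = )` (default 0.05 each).
#' @param volume_dist function `f(n)` drawing punctum volumes in um^3, or a
#'   list with elements `ribbon` and `receptor`. Default: lognormal with
#'   median 0.15 um^3, truncated to [0.06, 1.2] um^3 — inside the 0.04-5 um^3
#'   range admissible for a synapse.
#' @param cleft_um centre-to-centre offset between members of a pair
#'   (default 0.3 um).
#' @param region_label cochlear region carried as metadata:
#'   `"apex"` (4-12 kHz), `"middle"` (12-20 kHz) or `"base"` (22-40 kHz).
#' @param cell_ax,cell_ay cell footprint ellipse semi-axes in um.
#' @param cell_gap_um gap between adjacent cell footprints in um.
#' @param z_range_um z interval (um) in which puncta centres are placed.
#' @param seed integer seed; output is a pure function of arguments + seed.
#' @return an object of class `"ground_truth"`: list with `puncta`
#'   (data.frame: punctum_id, cell_id, channel, x_um, y_um, z_um, volume_um3,
#'   pair_id), `cells` (data.frame: cell_id, cx_um, cy_um, ax_um, ay_um,
#'   region_label), `field$extent_um`, `cleft_um`, `seed`.
#' @export
plant_ground_truth <- function(n_cells = 10, pairs_per_cell = 16,
                               orphan_rate = c(ribbon = 0.05, receptor = 0.05),
                               volume_dist = NULL, cleft_um = 0.3,
                               region_label = c("apex", "middle", "base"),
                               cell_ax = 4.2, cell_ay = 5.0,
                               cell_gap_um = 1.0, z_range_um = c(1.1, 3.1),
                               seed = 1) {
  abort_if(!is.numeric(n_cells) || n_cells < 1, "`n_cells` must be >= 1")
  n_cells <- as.integer(n_cells)
  region_label <- match.arg(region_label)
  if (length(orphan_rate) == 1L)
    orphan_rate <- c(ribbon = unname(orphan_rate), receptor = unname(orphan_rate))
  abort_if(any(orphan_rate < 0) || any(orphan_rate > 1),
           "`orphan_rate` entries must lie in [0, 1]")
  check_scalar_pos(cleft_um, "cleft_um")

  default_vol <- function(n) pmin(pmax(rlnorm(n, log(0.15), 0.35), 0.06), 1.2)
  if (is.null(volume_dist)) volume_dist <- default_vol
  if (is.function(volume_dist))
    volume_dist <- list(ribbon = volume_dist, receptor = volume_dist)

  if (is.function(pairs_per_cell)) {
    draw_pairs <- pairs_per_cell
  } else {
    k <- as.integer(pairs_per_cell)
    draw_pairs <- function(n) rep(k, n)
  }

  margin <- 2.0
  pitch <- 2 * cell_ax + cell_gap_um
  extent <- c(2 * margin + n_cells * pitch,
              2 * (cell_ay + margin),
              max(z_range_um) + min(z_range_um))

  withr::with_seed(seed, {
    cells <- data.frame(
      cell_id = seq_len(n_cells),
      cx_um = margin + pitch * (seq_len(n_cells) - 0.5),
      cy_um = cell_ay + margin,
      ax_um = cell_ax, ay_um = cell_ay,
      region_label = region_label,
      stringsAsFactors = FALSE)

    n_pairs <- draw_pairs(n_cells)
    abort_if(any(n_pairs < 0), "pairs_per_cell must be non-negative")

    rows <- list()
    pair_counter <- 0L
    punctum_counter <- 0L
    placed_xy <- matrix(numeric(0), ncol = 2)

    # parametric angles giving uniform spacing in arc length on the ellipse
    arc_uniform_thetas <- function(ax, ay, n, phase, jitter) {
      tt <- seq(0, 2 * pi, length.out = 2049L)
      seg <- sqrt((ax * diff(cos(tt)))^2 + (ay * diff(sin(tt)))^2)
      cum <- c(0, cumsum(seg))
      frac <- (((seq_len(n) - 1) + jitter) / n + phase) %% 1
      target <- cum[length(cum)] * frac
      vapply(target, function(s) tt[which.max(cum >= s)], numeric(1))
    }

    ring_point <- function(cell, theta) {
      r <- runif(1, 0.75, 0.95)
      c(cell$cx_um + r * cell$ax_um * cos(theta),
        cell$cy_um + r * cell$ay_um * sin(theta))
    }

    for (ci in seq_len(n_cells)) {
      cell <- cells[ci, ]
      np <- n_pairs[ci]
      n_orph <- c(ribbon = rbinom(1, np, orphan_rate[["ribbon"]]),
                  receptor = rbinom(1, np, orphan_rate[["receptor"]]))
      n_slots <- np + sum(n_orph)
      if (n_slots == 0) next
      thetas <- arc_uniform_thetas(cell$ax_um, cell$ay_um, n_slots,
                                   runif(1), runif(n_slots, -0.1, 0.1))
      slot_roles <- sample(c(rep("pair", np),
                             rep("ribbon_orphan", n_orph[["ribbon"]]),
                             rep("receptor_orphan", n_orph[["receptor"]])))
      for (si in seq_len(n_slots)) {
        xy <- ring_point(cell, thetas[si])
        z <- runif(1, z_range_um[1], z_range_um[2])
        role <- slot_roles[si]
        if (role == "pair") {
          pair_counter <- pair_counter + 1L
          # cleft direction: radially outward from the cell centre with a
          # random axial tilt, mimicking the receptor patch sitting just
          # outside/below the ribbon; keeps ring spacing intact.
          rv <- c(xy[1] - cell$cx_um, xy[2] - cell$cy_um)
          rv <- rv / sqrt(sum(rv^2))
          alpha <- runif(1, -pi / 3, pi / 3)
          u <- c(rv * cos(alpha), sin(alpha))
          for (ch in c("ribbon", "receptor")) {
            punctum_counter <- punctum_counter + 1L
            off <- if (ch == "ribbon") c(0, 0, 0) else cleft_um * u
            rows[[punctum_counter]] <- data.frame(
              punctum_id = punctum_counter, cell_id = cell$cell_id,
              channel = ch, x_um = xy[1] + off[1], y_um = xy[2] + off[2],
              z_um = z + off[3], volume_um3 = NA_real_,
              pair_id = pair_counter, stringsAsFactors = FALSE)
          }
        } else {
          ch <- if (role == "ribbon_orphan") "ribbon" else "receptor"
          punctum_counter <- punctum_counter + 1L
          rows[[punctum_counter]] <- data.frame(
            punctum_id = punctum_counter, cell_id = cell$cell_id,
            channel = ch, x_um = xy[1], y_um = xy[2], z_um = z,
            volume_um3 = NA_real_, pair_id = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }

    puncta <- if (length(rows)) do.call(rbind, rows) else
      data.frame(punctum_id = integer(), cell_id = integer(),
                 channel = character(), x_um = numeric(), y_um = numeric(),
                 z_um = numeric(), volume_um3 = numeric(),
                 pair_id = integer(), stringsAsFactors = FALSE)

    for (ch in c("ribbon", "receptor")) {
      idx <- which(puncta$channel == ch)
      if (length(idx)) {
        v <- volume_dist[[ch]](length(idx))
        abort_if(any(!is.finite(v)) || any(v <= 0),
                 "volume distribution produced values outside (0, Inf)")
        puncta$volume_um3[idx] <- v
      }
    }

    structure(list(puncta = puncta, cells = cells,
                   field = list(extent_um = extent),
                   cleft_um = cleft_um, seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d cells (%s), %d puncta (%d pairs, %d orphans), field %.1f x %.1f x %.1f um\n",
    nrow(x$cells), x$cells$region_label[1] %||% "?", nrow(x$puncta),
    length(unique(na.omit(x$puncta$pair_id))),
    sum(is.na(x$puncta$pair_id)),
    x$field$extent_um[1], x$field$extent_um[2], x$field$extent_um[3]))
  invisible(x)
}

# Per-cell planted counts: ribbons, receptors and pairs (the oracle counts
# that the counting pipeline is benchmarked against).
ground_truth_counts <- function(gt) {
  cells <- gt$cells$cell_id
  cnt <- function(ch) vapply(cells, function(ci)
    sum(gt$puncta$cell_id == ci & gt$puncta$channel == ch), integer(1))
  data.frame(cell_id = cells,
             n_ribbon = cnt("ribbon"),
             n_receptor = cnt("receptor"),
             n_colocalized = vapply(cells, function(ci)
               length(unique(na.omit(
                 gt$puncta$pair_id[gt$puncta$cell_id == ci]))), integer(1)))
}
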