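#' Loss score of a placed bead model
#'
#' Quadratic hinge penalties over four constraint families: interacting
#' bead pairs farther apart than touching, any pair of beads overlapping,
#' chain-adjacent beads (consecutive beads of a chromosome) farther apart
#' than touching, and beads protruding beyond the nuclear envelope. The
#' score is zero iff every constraint is satisfied:
#'
#' `w_i * sum max(0, d_ij - (r_i+r_j))^2  +  w_o * sum max(0, (r_i+r_j) - d_ij)^2
#'  +  w_c * sum max(0, d_ij - (r_i+r_j))^2  +  w_n * sum max(0, |c_i| + r_i - R)^2`
#'
#' @param model A placed [bead_model()].
#' @param weights Named numeric vector with entries `wi` (interaction),
#'   `wo` (overlap), `wc` (chain), `wn` (containment).
#' @return Non-negative scalar loss.
#' @export
model_loss <- function(model, weights = c(wi = 1, wo = 1, wc = 1, wn = 1)) {
  b <- model$beads
  if (any(is.na(b$x))) stop("all beads must be placed", call. = FALSE)
  xyz <- as.matrix(b[, c("x", "y", "z")])
  r <- b$radius
  R <- model$nucleus_radius
  n <- nrow(b)
  dmat <- as.matrix(stats::dist(xyz))
  rsum <- outer(r, r, "+")
  loss <- weights[["wn"]] * sum(pmax(0, sqrt(rowSums(xyz^2)) + r - R)^2)
  # overlap over unordered pairs
  ut <- upper.tri(dmat)
  loss <- loss + weights[["wo"]] * sum(pmax(0, rsum[ut] - dmat[ut])^2)
  ia <- match(model$interactions$bead_a, b$bead_id)
  ib <- match(model$interactions$bead_b, b$bead_id)
  if (length(ia)) {
    d <- dmat[cbind(ia, ib)]
    loss <- loss + weights[["wi"]] * sum(pmax(0, d - (r[ia] + r[ib]))^2)
  }
  adj <- chain_pairs(b)
  if (nrow(adj)) {
    d <- dmat[cbind(adj[, 1], adj[, 2])]
    loss <- loss +
      weights[["wc"]] * sum(pmax(0, d - (r[adj[, 1]] + r[adj[, 2]]))^2)
  }
  unname(loss)
}

# Row indices of consecutive beads within each chromosome.
chain_pairs <- function(beads) {
  idx <- seq_len(nrow(beads))
  same <- beads$chrom[-nrow(beads)] == beads$chrom[-1]
  if (nrow(beads) < 2L || !any(same)) {
    return(matrix(integer(0), ncol = 2))
  }
  cbind(idx[-nrow(beads)][same], idx[-1][same])
}

#' Random initial placement of a bead model
#'
#' Each chromosome's first bead is placed uniformly in the sphere of
#' admissible centres (`|c| <= R - r`); each subsequent bead is placed
#' touching its chain predecessor in a random direction, pulled back inside
#' the envelope if needed. Keeps chain-adjacent beads near-adjacent from the
#' start.
#'
#' @param model A [bead_model()].
#' @param seed Integer seed.
#' @return The model with coordinates filled in.
#' @export
initial_placement <- function(model, seed = NULL) {
  with_seed(seed, {
    b <- model$beads
    R <- model$nucleus_radius
    xyz <- matrix(0, nrow(b), 3)
    for (i in seq_len(nrow(b))) {
      if (i == 1L || b$chrom[i] != b$chrom[i - 1L]) {
        rmax <- max(R - b$radius[i], 0)
        xyz[i, ] <- random_direction() * rmax * stats::runif(1)^(1 / 3)
      } else {
        gap <- b$radius[i - 1L] + b$radius[i]
        xyz[i, ] <- xyz[i - 1L, ] + random_direction() * gap
        xyz[i, ] <- pull_inside(xyz[i, ], b$radius[i], R)
      }
    }
    model$beads$x <- xyz[, 1]
    model$beads$y <- xyz[, 2]
    model$beads$z <- xyz[, 3]
    model
  })
}

random_direction <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

pull_inside <- function(p, r, R) {
  d <- sqrt(sum(p^2))
  lim <- R - r
  if (d > lim && d > 0) p * (lim / d) else p
}

#' Optimize bead placement by Monte Carlo
#'
#' Metropolis single-bead moves against [model_loss()]: at each step one
#' bead is displaced by an isotropic Gaussian step and the move is accepted
#' if it lowers the loss, or with probability `exp(-delta / T)` under the
#' geometric temperature schedule `T_k = t0 * cooling^k` (greedy when
#' `t0 = 0`). Interacting pairs are thereby pulled toward contact while
#' overlap, chain, and containment penalties keep the configuration a
#' packed, contiguous polymer inside the nuclear envelope.
#'
#' @param model A [bead_model()]; unplaced models get [initial_placement()].
#' @param n_steps Number of proposed moves.
#' @param step_size Proposal standard deviation, um.
#' @param t0 Initial temperature (0 for pure greedy descent).
#' @param cooling Geometric cooling ratio per step.
#' @param t_floor Temperature below which acceptance is greedy.
#' @param weights Loss weights, see [model_loss()].
#' @param hard_envelope Treat the nuclear envelope as a hard constraint:
#'   moves that would place a bead partly outside the nucleus are rejected
#'   outright (the containment loss term still scores any violation, e.g.
#'   in a user-supplied placement). Default TRUE.
#' @param seed Integer seed; the run is fully reproducible.
#' @return The model with optimized coordinates plus elements `loss_trace`
#'   (loss after each accepted move, starting at the initial loss) and
#'   `final_loss`.
#' @export
optimize_model <- function(model, n_steps = 10000, step_size = 0.1,
                           t0 = 1, cooling = 0.999, t_floor = 1e-4,
                           weights = c(wi = 1, wo = 1, wc = 1, wn = 1),
                           hard_envelope = TRUE, seed = NULL) {
  with_seed(seed, {
    if (any(is.na(model$beads$x))) {
      model <- initial_placement(model, seed = NULL)
    }
    b <- model$beads
    n <- nrow(b)
    xyz <- as.matrix(b[, c("x", "y", "z")])
    r <- b$radius
    R <- model$nucleus_radius
    ia <- match(model$interactions$bead_a, b$bead_id)
    ib <- match(model$interactions$bead_b, b$bead_id)
    adj <- chain_pairs(b)
    # neighbour lists: for bead i, partners in interaction and chain terms
    int_nbr <- vector("list", n)
    for (k in seq_along(ia)) {
      int_nbr[[ia[k]]] <- c(int_nbr[[ia[k]]], ib[k])
      int_nbr[[ib[k]]] <- c(int_nbr[[ib[k]]], ia[k])
    }
    chain_nbr <- vector("list", n)
    if (nrow(adj)) {
      for (k in seq_len(nrow(adj))) {
        chain_nbr[[adj[k, 1]]] <- c(chain_nbr[[adj[k, 1]]], adj[k, 2])
        chain_nbr[[adj[k, 2]]] <- c(chain_nbr[[adj[k, 2]]], adj[k, 1])
      }
    }
    local_loss <- function(i, p) {
      d2 <- sqrt(colSums((t(xyz) - p)^2))
      d2[i] <- Inf
      l <- weights[["wo"]] * sum(pmax(0, (r + r[i]) - d2)^2) +
        weights[["wn"]] * max(0, sqrt(sum(p^2)) + r[i] - R)^2
      if (length(int_nbr[[i]])) {
        j <- int_nbr[[i]]
        l <- l + weights[["wi"]] * sum(pmax(0, d2[j] - (r[j] + r[i]))^2)
      }
      if (length(chain_nbr[[i]])) {
        j <- chain_nbr[[i]]
        l <- l + weights[["wc"]] * sum(pmax(0, d2[j] - (r[j] + r[i]))^2)
      }
      l
    }
    loss <- model_loss(model, weights)
    trace <- numeric(n_steps + 1L)
    trace[1L] <- loss
    n_acc <- 0L
    temp <- t0
    if (n_steps > 0) {
      for (step in seq_len(n_steps)) {
        i <- sample.int(n, 1L)
        prop <- xyz[i, ] + stats::rnorm(3, sd = step_size)
        if (hard_envelope &&
            sqrt(sum(prop^2)) + r[i] > R) {
          temp <- temp * cooling
          next
        }
        delta <- local_loss(i, prop) - local_loss(i, xyz[i, ])
        accept <- delta < 0 ||
          (temp > t_floor && stats::runif(1) < exp(-delta / temp))
        if (accept) {
          xyz[i, ] <- prop
          loss <- loss + delta
          n_acc <- n_acc + 1L
          trace[n_acc + 1L] <- loss
        }
        temp <- temp * cooling
      }
    }
    model$beads$x <- xyz[, 1]
    model$beads$y <- xyz[, 2]
    model$beads$z <- xyz[, 3]
    # recompute exactly to shed accumulated floating-point drift
    model$final_loss <- model_loss(model, weights)
    model$loss_trace <- trace[seq_len(n_acc + 1L)]
    model
  })
}

#' Assign placed beads to radial shells
#'
#' A bead belongs to the shell of its centre: distance `d` from the nuclear
#' centre falls in the half-open bin `[k, k+1)` labeled `"k-(k+1)"` (for
#' 1-um shells).
#'
#' @param model A placed [bead_model()].
#' @param shell_width_um Shell width, um.
#' @return Data.frame `bead_id, shell, radial_um`.
#' @export
assign_shells <- function(model, shell_width_um = 1) {
  b <- model$beads
  if (any(is.na(b$x))) stop("beads must be placed", call. = FALSE)
  d <- sqrt(b$x^2 + b$y^2 + b$z^2)
  if (any(d >= model$nucleus_radius)) {
    stop("bead centre outside the nucleus", call. = FALSE)
  }
  k <- floor(d / shell_width_um)
  lab <- paste0(format_num(k * shell_width_um), "-",
                format_num((k + 1) * shell_width_um))
  data.frame(bead_id = b$bead_id, shell = lab, radial_um = d,
             stringsAsFactors = FALSE)
}

#' Export / import a placed model as a plain-text table
#'
#' One row per bead: `chrom, start, end, bead_id, type, x, y, z, radius,
#' shell`. Header comment lines carry the nucleus radius and occupancy so
#' the table round-trips through [import_model()].
#'
#' @param model A placed [bead_model()].
#' @param assignment Optional shell assignment from [assign_shells()].
#' @param path Output path; when NULL the data.frame is returned only.
#' @return The exported data.frame, invisibly when written to `path`.
#' @export
export_model <- function(model, assignment = NULL, path = NULL) {
  b <- model$beads
  df <- data.frame(chrom = b$chrom, start = b$start, end = b$end,
                   bead_id = b$bead_id, type = b$type,
                   x = b$x, y = b$y, z = b$z, radius = b$radius,
                   stringsAsFactors = FALSE)
  df$shell <- if (is.null(assignment)) {
    rep(NA_character_, nrow(b))
  } else {
    assignment$shell[match(b$bead_id, assignment$bead_id)]
  }
  if (is.null(path)) return(df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# nucleus_radius_um=", format(model$nucleus_radius, digits = 15)),
    paste0("# occupancy=", format(model$occupancy, digits = 15))
  ), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(df)
}

#' @rdname export_model
#' @export
import_model <- function(path) {
  hdr <- readLines(path, n = 2L)
  getval <- function(key) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    as.numeric(sub(paste0("# ", key, "="), "", line))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  beads <- df[, c("chrom", "start", "end", "bead_id", "type")]
  beads$length_bp <- beads$end - beads$start
  beads$radius <- df$radius
  beads$x <- df$x; beads$y <- df$y; beads$z <- df$z
  model <- structure(
    list(beads = beads, nucleus_radius = getval("nucleus_radius_um"),
         occupancy = getval("occupancy"),
         interactions = data.frame(bead_a = integer(), bead_b = integer())),
    class = "bead_model"
  )
  assignment <- NULL
  if (!all(is.na(df$shell))) {
    assignment <- data.frame(
      bead_id = df$bead_id, shell = df$shell,
      radial_um = sqrt(df$x^2 + df$y^2 + df$z^2),
      stringsAsFactors = FALSE
    )
  }
  list(model = model, assignment = assignment)
}
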