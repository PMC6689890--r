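#' t-SNE embedding of fingerprint space
#'
#' Exact (non-approximate) t-distributed stochastic neighbor embedding of a
#' fingerprint matrix into two components, `CSNE1` and `CSNE2`. Pairwise
#' affinities are Gaussian on squared Euclidean bit distances with per-point
#' bandwidths calibrated to `perplexity` by binary search; the embedding is
#' optimized by gradient descent with momentum and early exaggeration.
#' Deterministic given `seed`.
#'
#' @param fps 0/1 fingerprint matrix (conventionally folded to 2048 bits for
#'   embedding), rownames = compound ids.
#' @param perplexity effective neighborhood size; requires
#'   `nrow(fps) > 3 * perplexity`.
#' @param seed integer seed for the random initialization.
#' @param maxIter gradient-descent iterations.
#' @return an [EmbeddingResult].
#' @export
embedTsne <- function(fps, perplexity = 30, seed = 1L, maxIter = 500L) {
  n <- nrow(fps)
  if (n <= 3 * perplexity)
    stop(sprintf("perplexity %g too large for n = %d (need n > 3*perplexity)",
                 perplexity, n))
  D2 <- as.matrix(stats::dist(fps))^2

  # per-point bandwidth by binary search on perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sumP) + beta * sum(di * p) / sumP
        p <- p / sumP
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps

  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  exaggeration <- 12
  # adaptive learning rate; a fixed large step diverges at small n
  eta <- max(n / (4 * exaggeration), 50)
  Pe <- P * exaggeration
  for (iter in seq_len(maxIter)) {
    if (iter == 101) Pe <- P
    if (iter == 251) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- c("CSNE1", "CSNE2")
  rownames(Y) <- rownames(fps)
  new("EmbeddingResult", coords = Y, perplexity = perplexity,
      seed = as.integer(seed))
}

#' Per-source physicochemical summary
#'
#' Mean and standard deviation of molecular weight, ALogP, H-bond donor and
#' H-bond acceptor counts, grouped by compound source. Empty source groups
#' are omitted with a warning.
#'
#' @param compounds a [CompoundSet].
#' @param physchem optional precomputed [physchemBlock()] matrix (rownames =
#'   compound ids); computed when `NULL`.
#' @return `data.frame`, one row per source: `source, n, MW_mean, MW_sd,
#'   ALogP_mean, ALogP_sd, HBD_mean, HBD_sd, HBA_mean, HBA_sd`.
#' @export
physchemSummary <- function(compounds, physchem = NULL) {
  cd <- compoundData(compounds)
  if (is.null(physchem))
    physchem <- physchemBlock(setNames(cd$smiles, cd$compound_id))
  physchem <- physchem[match(cd$compound_id, rownames(physchem)), , drop = FALSE]
  present <- unique(cd$source)
  absent <- setdiff(.SOURCES, present)
  if (length(absent) && length(present) < length(.SOURCES))
    warning("empty source group(s) omitted: ", paste(absent, collapse = ", "),
            call. = FALSE)
  rows <- lapply(present, function(s) {
    m <- physchem[cd$source == s, , drop = FALSE]
    one <- function(col) {
      v <- m[, col]
      c(mean(v), if (length(v) > 1) sd(v) else 0)
    }
    data.frame(source = s, n = nrow(m),
               MW_mean = one("MW")[1], MW_sd = one("MW")[2],
               ALogP_mean = one("ALogP")[1], ALogP_sd = one("ALogP")[2],
               HBD_mean = one("HBD")[1], HBD_sd = one("HBD")[2],
               HBA_mean = one("HBA")[1], HBA_sd = one("HBA")[2])
  })
  do.call(rbind, rows)
}

#' Cluster active compounds into candidate binding-mode groups
#'
#' k-medoid (PAM) clustering of actives on the Tanimoto distance of their
#' circular fingerprints. Intended for the permissive active definition
#' (percent-of-control < 70 for in-house records, pChEMBL >= 6.5 for public
#' records - deliberately looser than the modelling cutoff so weak binders
#' are included). With `k >= n`, every compound becomes its own singleton
#' cluster with a warning.
#'
#' @param fps fingerprint matrix of the actives, rownames = compound ids.
#' @param k number of clusters (default 10).
#' @param physchem optional [physchemBlock()] matrix for per-cluster
#'   property summaries.
#' @return list: `assignments` (named integer vector over all actives),
#'   `medoids` (compound ids), optional `properties` (per-cluster mean MW /
#'   ALogP / HBD / HBA).
#' @export
clusterActives <- function(fps, k = 10L, physchem = NULL) {
  n <- nrow(fps)
  if (k >= n) {
    if (k > n) warning("k exceeds number of actives; one singleton cluster per compound",
                       call. = FALSE)
    assignments <- setNames(seq_len(n), rownames(fps))
    medoids <- rownames(fps)
  } else {
    d <- stats::as.dist(1 - tanimoto(fps))
    pm <- cluster::pam(d, k = k, pamonce = 5)
    assignments <- setNames(pm$clustering, rownames(fps))
    medoids <- rownames(fps)[pm$id.med]
  }
  out <- list(assignments = assignments, medoids = medoids)
  if (!is.null(physchem)) {
    physchem <- physchem[match(names(assignments), rownames(physchem)), ,
                         drop = FALSE]
    props <- aggregate(physchem[, c("MW", "ALogP", "HBD", "HBA"), drop = FALSE],
                       by = list(cluster = assignments), FUN = mean)
    out$properties <- props
  }
  out
}

#' Selecting actives for clustering
#'
#' Applies the permissive active definition used for binding-mode
#' exploration: in-house percent-of-control strictly below `percentCutoff`,
#' public pChEMBL at or above `pchemblFloor` (note: inclusive, and lower
#' than the modelling cutoff).
#'
#' @param activities an [ActivitySet].
#' @param targetId primary target.
#' @param percentCutoff in-house cutoff (default 70, exclusive).
#' @param pchemblFloor public floor (default 6.5, inclusive).
#' @return character vector of active compound ids (unique).
#' @export
activeCompoundIds <- function(activities, targetId, percentCutoff = 70,
                              pchemblFloor = 6.5) {
  d <- activityData(activities)
  d <- d[d$target_id == targetId, , drop = FALSE]
  act <- (d$dialect == "percent_control" & d$value < percentCutoff) |
    (d$dialect == "pchembl" & d$value >= pchemblFloor)
  unique(d$compound_id[act])
}

#' Write an embedding to CSV
#'
#' @param x an [EmbeddingResult].
#' @param path output CSV.
#' @export
writeEmbedding <- function(x, path) {
  d <- data.frame(compound_id = rownames(embeddingCoords(x)),
                  embeddingCoords(x))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
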