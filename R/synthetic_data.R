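# Fragment grammars -----------------------------------------------------------
#
# Compounds are assembled from scaffold templates with R1/R2 slots filled by
# attachable substituent fragments. The glycoside-like grammar emulates a
# polyol-rich (high HBD/HBA) chemical space of aryl/alkyl glycosides; the
# diverse grammar spans drug-like scaffolds from MW ~150 to ~700.
# Activity is planted through motif substituents recognized by SMARTS rules;
# decoy substituents of comparable size keep molecular weight uninformative
# on its own.

# Substituent fragments use ring-closure digits 8/9 so they can be spliced
# into scaffolds (which use digits 1/2) without ring-number collisions.
# Every scaffold carries two slots: R1 is filled from the substituent pool,
# R2 from the pool or (with probability rule_attach_prob) from the motif
# variants that the grammar's SMARTS rule recognizes.
.GRAMMARS <- list(
  glycoside_like = list(
    scaffolds = c("OCC1OC(R2)C(O)C(R1)C1O",
                  "OC1C(R1)C(O)C(CO)OC1R2",
                  "OCC1OC(R2)C(R1)C(O)C1O",
                  "OCC1OC(OC2OC(CO)C(R1)C(O)C2O)C(R2)C(O)C1O",
                  "OCC1NC(R2)C(O)C(R1)C1O",
                  "OCC1CC(R2)C(O)C(R1)C1O"),
    r1 = c("O", "N", "C", "CO", "OC", "F"),
    substituents = c("Oc9ccccc9", "Oc9ccc(C)cc9", "Oc9ccc(OC)cc9", "OCC",
                     "OCCC", "Oc9ccc8ccccc8c9", "OCCc9ccccc9", "OC(C)C",
                     "Oc9ccc(CC)cc9", "SC", "Oc9ccc(C(=O)C)cc9",
                     "Oc9cccc(C)c9", "OCc9ccccc9", "Oc9ccc(O)cc9", "OC",
                     "Oc9ccc(N)cc9"),
    motifs = c("Oc8ccc(C(=O)c9ccccc9)cc8", "Oc8ccc(C(=O)c9ccc(C)cc9)cc8",
               "Oc8ccc(C(=O)c9ccc(O)cc9)cc8", "Oc8cc(C)ccc8C(=O)c9ccccc9")),
  diverse = list(
    scaffolds = c("c1cc(R1)ccc1R2", "C1CC(R1)CCN1R2",
                  "c1ccc2cc(R2)c(R1)cc2c1", "O=C(R2)N1CCCC1R1",
                  "COc1cc(R1)ccc1R2", "C(R1)(R2)c1ccccc1",
                  "O=C(Nc1ccc(R1)cc1)R2", "CN(Cc1ccc(R1)cc1)R2",
                  "O=S(=O)(N(C)C)c1cc(R1)ccc1R2", "OC(=O)C(R2)c1ccc(R1)cc1",
                  "C1CN(R2)CCN1R1", "c1cc(R1)ccc1CCNC(=O)R2"),
    r1 = NULL,
    substituents = c("C", "CC", "CCC", "C(C)C", "CCO", "CO", "Cl",
                     "C(F)(F)F", "OC", "N(C)C", "CCN(C)C", "c9ccccc9",
                     "Cc9ccccc9", "OCC", "C#N", "C(=O)OC", "CCc9ccccc9",
                     "CCN9CCCCC9", "OC9CCCCC9", "CCOCC"),
    motifs = c("CCN9CCC(O)CC9", "CN9CCC(O)CC9", "CCCN9CCC(O)CC9",
               "CCN9CCC(O)(C)CC9")))

# SMARTS rules recognizing the planted motifs: a diaryl-ketone glycoside
# pharmacophore for the glycoside-like space, a 4-hydroxypiperidine for the
# diverse space. Patterns are chosen so that neither grammar can produce the
# other grammar's motif.
.DEFAULT_RULES <- list(
  glycoside = list(pattern = "O=C(c1ccccc1)c1ccccc1", contribution = 3.6),
  diverse = list(pattern = "OC1CCN(C)CC1", contribution = 3.8))

.DEFAULT_TARGETS <- data.frame(
  target_id = c("SGLT1_hs", "SGLT2_hs", "SGLT3_hs", "SGLT1_rn",
                "SGLT2_rn", "SGLT1_mm", "SGLT2_mm", "SGLT3_mm"),
  species = c("hs", "hs", "hs", "rn", "rn", "mm", "mm", "mm"),
  stringsAsFactors = FALSE)

#' Synthetic-data generator configuration
#'
#' Defaults define the emulated study conditions: an 8-member SGLT-like
#' panel, roughly 600 public pChEMBL records concentrated in a narrow
#' glycoside-like chemotype, roughly 1500 in-house percent-of-control
#' records over a diverse chemotype measured on two panel members, and a
#' diverse screening library. Activity follows a latent potency
#' \eqn{baseline + \sum rule\ contributions + target\ modifier + noise},
#' emitted as pChEMBL = clip(latent, 4, 10) for the public dialect and as
#' percent-of-control \eqn{100 - g(latent)} for the in-house dialect, with
#' `g` a logistic scaled to \[0, 100\].
#'
#' @param seed integer master seed.
#' @param n_public_compounds,n_inhouse_compounds,n_library set sizes.
#' @param panel_size number of panel proteins.
#' @param sequence_length alignment width (residues; no indels are
#'   generated, so sequences arrive pre-aligned).
#' @param mutation_rate i.i.d. per-position substitution rate between the
#'   panel root and each member.
#' @param pharmacophore_rules named list of `list(pattern, contribution)`.
#' @param rule_attach_prob probability a generated compound carries its
#'   grammar's motif substituent.
#' @param baseline latent potency with no rule matched (pChEMBL-like units).
#' @param noise_sd latent Gaussian noise.
#' @param zweight weights of the target mean z-scales in the target
#'   modifier.
#' @param percent_g_mid,percent_g_scale location/scale of the logistic
#'   latent-to-percent link.
#' @param percent_floor,percent_ceiling clipping bounds of the percent
#'   dialect.
#' @return a list of class `pcm_generator_config`.
#' @export
generatorConfig <- function(seed = 1L,
                            n_public_compounds = 300L,
                            n_inhouse_compounds = 750L,
                            n_library = 500L,
                            panel_size = 8L,
                            sequence_length = 400L,
                            mutation_rate = 0.05,
                            pharmacophore_rules = .DEFAULT_RULES,
                            rule_attach_prob = 0.15,
                            baseline = 5.0,
                            noise_sd = 0.8,
                            zweight = c(0.08, 0.06, -0.05),
                            percent_g_mid = 7.8,
                            percent_g_scale = 1.5,
                            percent_floor = 2,
                            percent_ceiling = 100) {
  stopifnot(panel_size >= 2, mutation_rate >= 0, mutation_rate <= 1,
            rule_attach_prob >= 0, rule_attach_prob <= 1,
            length(pharmacophore_rules) >= 1,
            all(is.finite(vapply(pharmacophore_rules, `[[`, 0, "contribution"))))
  structure(as.list(environment()), class = "pcm_generator_config")
}

#' Generate an aligned synthetic protein panel
#'
#' One random root sequence; each panel member is derived by i.i.d.
#' substitutions (to a uniformly drawn residue, so a fraction 1/20 of drawn
#' substitutions are silent) at `mutation_rate`. Sequences are emitted
#' pre-aligned: equal length, no indels.
#'
#' @param config a [generatorConfig()].
#' @return a [ProteinPanel].
#' @export
generatePanel <- function(config) {
  set.seed(config$seed + 101L)
  aas <- rownames(.zscaleMatrix())
  root <- sample(aas, config$sequence_length, replace = TRUE)
  n <- config$panel_size
  if (n == nrow(.DEFAULT_TARGETS)) {
    ids <- .DEFAULT_TARGETS$target_id
    species <- .DEFAULT_TARGETS$species
  } else {
    ids <- sprintf("SGLT%d_syn", seq_len(n))
    species <- rep("syn", n)
  }
  seqs <- vapply(seq_len(n), function(i) {
    s <- root
    if (i > 1) {
      hit <- runif(length(s)) < config$mutation_rate
      s[hit] <- sample(aas, sum(hit), replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
  ProteinPanel(ids, seqs, species = species)
}

#' Generate synthetic compounds from a fragment grammar
#'
#' Samples scaffold/substituent combinations from the requested grammar,
#' plants the grammar's activity motif with probability
#' `config$rule_attach_prob`, standardizes every structure and returns
#' unique compounds. If the grammar cannot supply enough unique structures,
#' sampling continues with replacement under a warning.
#'
#' @param config a [generatorConfig()].
#' @param style `"glycoside_like"` or `"diverse"`.
#' @param n number of compounds; defaults to the config's set size for the
#'   style (`n_public_compounds` / `n_inhouse_compounds`).
#' @param idPrefix compound id prefix.
#' @param source provenance tag for the [CompoundSet].
#' @param seedOffset offset added to the master seed.
#' @return a [CompoundSet] of standardized compounds.
#' @export
generateCompounds <- function(config, style = c("diverse", "glycoside_like"),
                              n = NULL, idPrefix = "SYN", source = "public",
                              seedOffset = 0L) {
  style <- match.arg(style)
  g <- .GRAMMARS[[style]]
  if (is.null(n))
    n <- if (style == "glycoside_like") config$n_public_compounds
         else config$n_inhouse_compounds
  set.seed(config$seed + 211L + seedOffset)
  r1pool <- if (is.null(g$r1)) g$substituents else g$r1
  draw <- function(m) {
    scaf <- sample(g$scaffolds, m, replace = TRUE)
    sub1 <- sample(r1pool, m, replace = TRUE)
    sub2 <- sample(g$substituents, m, replace = TRUE)
    motif <- runif(m) < config$rule_attach_prob
    sub2[motif] <- sample(g$motifs, sum(motif), replace = TRUE)
    smi <- scaf
    for (i in seq_len(m)) {
      smi[i] <- sub("R1", sub1[i], smi[i], fixed = TRUE)
      smi[i] <- sub("R2", sub2[i], smi[i], fixed = TRUE)
    }
    smi
  }
  raw <- draw(2L * n)
  std <- unique(standardizeStructure(raw, onError = "drop"))
  if (length(std) < n) {
    warning("grammar exhausted; sampling with replacement", call. = FALSE)
    std <- sample(std, n, replace = TRUE)
  } else {
    std <- std[seq_len(n)]
  }
  CompoundSet(sprintf("%s%05d", idPrefix, seq_len(n)), unname(std),
              source = source)
}

# logistic latent-to-percent link, scaled to [0, 100]
.percentLink <- function(latent, config) {
  100 - 100 * plogis((latent - config$percent_g_mid) / config$percent_g_scale)
}

# match each rule against each compound; returns a logical matrix
.ruleMatches <- function(smiles, rules) {
  sdf <- ChemmineR::smiles2sdf(setNames(smiles, paste0("m", seq_along(smiles))))
  out <- vapply(rules, function(r)
    ChemmineR::smartsSearchOB(sdf, r$pattern, uniqueMatches = TRUE) > 0,
    logical(length(smiles)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(smiles))
  colnames(out) <- names(rules)
  out
}

# target modifier: inner product of the target's mean z-scales with a fixed
# weight vector
.targetModifiers <- function(panel, config) {
  vapply(targetIds(panel), function(t)
    sum(zscaleDescriptor(panel, t, mode = "sequence_mean") * config$zweight), 0)
}

#' Assign planted activities to compounds
#'
#' Latent potency = baseline + sum of matched rule contributions + target
#' modifier + Gaussian noise. The public dialect emits pChEMBL =
#' clip(latent, 4, 10) with confidence scores drawn from \{7, 9\}; the
#' in-house dialect emits percent-of-control = clip(100 - g(latent), floor,
#' ceiling) for the logistic link g.
#'
#' @param compounds a [CompoundSet].
#' @param panel a [ProteinPanel].
#' @param config a [generatorConfig()].
#' @param dialect `"pchembl"` or `"percent_control"`.
#' @param targetsPer how targets are assigned: `"weighted"` samples two
#'   distinct targets per compound with panel positions 1-2 favored
#'   (public-style coverage); `"primary_pair"` measures every compound on
#'   the first two panel targets (in-house-style screen).
#' @param seedOffset offset added to the master seed.
#' @return an [ActivitySet]; the latent potencies and rule-match matrix are
#'   attached as attributes `latent` and `matches`.
#' @export
assignActivities <- function(compounds, panel, config,
                             dialect = c("pchembl", "percent_control"),
                             targetsPer = c("weighted", "primary_pair"),
                             seedOffset = 0L) {
  dialect <- match.arg(dialect)
  targetsPer <- match.arg(targetsPer)
  cd <- compoundData(compounds)
  set.seed(config$seed + 307L + seedOffset)
  matches <- .ruleMatches(cd$smiles, config$pharmacophore_rules)
  contrib <- as.numeric(matches %*%
                          vapply(config$pharmacophore_rules, `[[`, 0, "contribution"))
  mods <- .targetModifiers(panel, config)
  tids <- targetIds(panel)
  if (targetsPer == "primary_pair") {
    tgt <- matrix(rep(tids[1:2], each = nrow(cd)), ncol = 2)
  } else {
    w <- c(4, 2, rep(1, length(tids) - 2))[seq_along(tids)]
    tgt <- t(vapply(seq_len(nrow(cd)),
                    function(i) sample(tids, 2, prob = w), c("", "")))
  }
  ids <- rep(cd$compound_id, 2)
  targets <- c(tgt[, 1], tgt[, 2])
  latent <- config$baseline + rep(contrib, 2) + mods[targets] +
    rnorm(length(ids), sd = config$noise_sd)
  if (dialect == "pchembl") {
    value <- pmin(pmax(latent, 4), 10)
    a <- ActivitySet(ids, targets, "pchembl",
                     sample(c("Ki", "IC50"), length(ids), replace = TRUE,
                            prob = c(0.6, 0.4)),
                     value,
                     sample(c(7L, 9L), length(ids), replace = TRUE,
                            prob = c(0.3, 0.7)))
  } else {
    value <- pmin(pmax(.percentLink(latent, config), config$percent_floor),
                  config$percent_ceiling)
    a <- ActivitySet(ids, targets, "percent_control", "percent", value)
  }
  attr(a, "latent") <- setNames(latent, paste(ids, targets))
  attr(a, "matches") <- matches
  a
}

#' The percent threshold the generator plants
#'
#' Under the default single-dominant-rule conditions, the in-house latent
#' potency is a two-component Gaussian mixture (non-matchers at `baseline`,
#' matchers at `baseline + contribution`). The class-conditional densities
#' cross at
#' \eqn{L^* = baseline + c/2 + (\sigma^2 / c)\,\log((1-\pi)/\pi)}
#' and the planted percent threshold is that point mapped through the
#' logistic link, \eqn{t^* = 100 - g(L^*)}: the percent cutoff that best
#' separates the structurally active class.
#'
#' @param config a [generatorConfig()].
#' @param matchedFraction realized fraction of in-house compounds matching
#'   the dominant rule; defaults to `config$rule_attach_prob`.
#' @param rule name of the dominant rule (default `"diverse"`).
#' @return the planted percent threshold.
#' @export
plantedPercentThreshold <- function(config, matchedFraction = NULL,
                                    rule = "diverse") {
  if (is.null(matchedFraction)) matchedFraction <- config$rule_attach_prob
  c0 <- config$pharmacophore_rules[[rule]]$contribution
  lstar <- config$baseline + c0 / 2 +
    (config$noise_sd^2 / c0) * log((1 - matchedFraction) / matchedFraction)
  .percentLink(lstar, config)
}

#' Generate a complete synthetic study dataset
#'
#' Builds the protein panel, a glycoside-like public dataset (pChEMBL
#' dialect, weighted target coverage), a diverse in-house dataset
#' (percent-of-control dialect, measured on the first two panel targets)
#' and a diverse screening library.
#'
#' @param config a [generatorConfig()].
#' @return list with `panel`, `public` (`compounds`, `activities`),
#'   `inhouse` (`compounds`, `activities`), `library` ([CompoundSet]) and
#'   `config`.
#' @export
generateDataset <- function(config = generatorConfig()) {
  panel <- generatePanel(config)
  pubC <- generateCompounds(config, "glycoside_like", idPrefix = "PUB",
                            source = "public", seedOffset = 0L)
  inhC <- generateCompounds(config, "diverse", idPrefix = "IH",
                            source = "in_house", seedOffset = 7L)
  libC <- generateCompounds(config, "diverse", n = config$n_library,
                            idPrefix = "LIB", source = "library",
                            seedOffset = 13L)
  pubA <- assignActivities(pubC, panel, config, "pchembl", "weighted",
                           seedOffset = 0L)
  inhA <- assignActivities(inhC, panel, config, "percent_control",
                           "primary_pair", seedOffset = 7L)
  list(panel = panel,
       public = list(compounds = pubC, activities = pubA),
       inhouse = list(compounds = inhC, activities = inhA),
       library = libC, config = config)
}

#' Write a complete demo workspace of fixture files
#'
#' Emits exactly the dialects the readers consume: `public.smi` /
#' `inhouse.smi` / `library.smi` (id-tab-SMILES), `public_activities.csv` /
#' `inhouse_activities.csv`, and `panel.fasta` (aligned FASTA with
#' `target|species` headers).
#'
#' @param config a [generatorConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
writeFixtures <- function(config = generatorConfig(), dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generateDataset(config)
  paths <- character(0)
  wsmi <- function(cs, file) {
    d <- compoundData(cs)
    writeLines(paste(d$compound_id, d$smiles, sep = "\t"), file.path(dir, file))
    file.path(dir, file)
  }
  wact <- function(as, file) {
    write.csv(activityData(as), file.path(dir, file), row.names = FALSE)
    file.path(dir, file)
  }
  paths <- c(wsmi(ds$public$compounds, "public.smi"),
             wsmi(ds$inhouse$compounds, "inhouse.smi"),
             wsmi(ds$library, "library.smi"),
             wact(ds$public$activities, "public_activities.csv"),
             wact(ds$inhouse$activities, "inhouse_activities.csv"))
  aln <- alignment(ds$panel)
  names(aln) <- paste(targetIds(ds$panel), ds$panel@species, sep = "|")
  fa <- file.path(dir, "panel.fasta")
  Biostrings::writeXStringSet(aln, fa)
  invisible(c(paths, fa))
}
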