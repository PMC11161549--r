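#' Read an amino-acid FASTA file
#'
#' Thin wrapper around \code{Biostrings::readAAStringSet} that uppercases
#' sequences, rejects duplicate record ids and rejects gap or non-amino-acid
#' characters (the drift model operates on fixed-length gap-free alignments).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences, in file order.
#' @export
readFastaAA <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  for (i in seq_along(seqs)) .checkAASeq(seqs[i], ids[i])
  seqs
}

#' Write amino-acid sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path (lines wrapped at 60 characters).
#' @export
writeFastaAA <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Generate a synthetic germline/bnAb/BCR sequence fixture
#'
#' Builds a random amino-acid triplet set with a prescribed V-segment
#' partition: germline and bnAb agree at exactly \code{L1} positions (chosen
#' at random) and differ at the remaining \code{L2}.  Each BCR starts from
#' the germline and receives a seeded random number of point substitutions;
#' its ground-truth compartment counts are tallied during generation.
#'
#' @param L1,L2 matched / mismatched position-set sizes (L1 + L2 <= 500).
#' @param nBcr number of BCR records (may be 0).
#' @param nMutRange integer range for the per-BCR mutation load.
#' @param seed integer root seed.
#' @return list with \code{sequences} (named character vector: germline,
#'   bnab, bcr_1, ...) and \code{truth} (data.frame of per-BCR states, N and
#'   Delta).
#' @examples
#' fx <- generateFixture(10, 5, nBcr = 2, seed = 1)
#' partitionFromSequences(fx$sequences[["germline"]],
#'                        fx$sequences[["bnab"]])
#' @export
generateFixture <- function(L1, L2, nBcr = 3, nMutRange = c(1, 10),
                            seed = 1) {
  L <- L1 + L2
  stopifnot(L >= 1, L <= 500, nBcr >= 0)
  withSeed(substreamSeed(seed, "generateFixture"), {
    germ <- sample(.AA, L, replace = TRUE)
    V2 <- sort(sample.int(L, L2))
    bnab <- germ
    for (p in V2) bnab[p] <- sample(setdiff(.AA, germ[p]), 1)
    seqs <- c(germline = paste(germ, collapse = ""),
              bnab = paste(bnab, collapse = ""))
    truth <- NULL
    for (i in seq_len(nBcr)) {
      bcr <- germ
      nm <- sample(seq(nMutRange[1], min(nMutRange[2], L)), 1)
      pos <- sample.int(L, nm)
      for (p in pos) bcr[p] <- sample(setdiff(.AA, bcr[p]), 1)
      # ground-truth tally, per position
      inV2 <- seq_len(L) %in% V2
      l11 <- sum(!inV2 & bcr == germ)
      l12 <- sum(!inV2 & bcr != germ)
      l21 <- sum(inV2 & bcr == germ)
      l22 <- sum(inV2 & bcr == bnab)
      l23 <- sum(inV2 & bcr != germ & bcr != bnab)
      truth <- rbind(truth,
                     data.frame(id = paste0("bcr_", i), l11 = l11, l12 = l12,
                                l21 = l21, l22 = l22, l23 = l23,
                                N = l12 + l22 + l23, Delta = l22 - l12))
      seqs[paste0("bcr_", i)] <- paste(bcr, collapse = "")
    }
    list(sequences = seqs, truth = truth)
  })
}

#' Read a run configuration file
#'
#' Parses a YAML configuration with optional sections \code{immigration}
#' (form, r0, gamma, weights, table), \code{model} (list of per-type
#' \code{types} entries with p0, pair_probs and a lifespan spec),
#' \code{simulation} (horizon, seed, cap, grid_step, replicates),
#' \code{fitness} (type, min, max, value) and \code{drift} (kernel
#' coefficients plus either L1/L2 or a FASTA path).  Each section is
#' validated by its owning constructor before anything is simulated.
#'
#' @param path YAML file path.
#' @return list with any of \code{spec}, \code{weights}, \code{model},
#'   \code{simulation}, \code{fitness}, \code{kernel}, \code{partition},
#'   plus the \code{raw} parsed list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(raw = raw)
  if (!is.null(raw$immigration)) {
    im <- raw$immigration
    out$spec <- rateSpec(form = im$form %||% "constant",
                         r0 = im$r0 %||% 1, gamma = im$gamma %||% 0,
                         table = if (!is.null(im$table))
                           matrix(unlist(im$table), ncol = 2, byrow = TRUE))
    if (!is.null(im$weights)) {
      w <- if (identical(im$weights, "distinct")) "distinct"
           else as.numeric(unlist(im$weights))
      checkTypeWeights(w)
      out$weights <- w
    }
  }
  if (!is.null(raw$model)) {
    types <- raw$model$types
    K <- length(types)
    offspring <- lifespan <- vector("list", K)
    for (k in seq_len(K)) {
      tp <- types[[k]]
      q <- if (!is.null(tp$pair_probs))
        matrix(unlist(tp$pair_probs), K, K, byrow = TRUE)
      else { m <- matrix(0, K, K); m[k, k] <- 1; m }
      offspring[[k]] <- offspringLaw(tp$p0, q)
      ls <- tp$lifespan %||% list(family = "exponential", rate = 1)
      lifespan[[k]] <- switch(ls$family,
        exponential = expLifespan(ls$rate),
        gamma = gammaLifespan(ls$shape, ls$scale),
        fixed = fixedLifespan(ls$value),
        stop("unknown lifespan family in config: ", ls$family))
    }
    out$model <- branchingModel(offspring, lifespan, K = K)
  }
  if (!is.null(raw$fitness)) {
    ft <- raw$fitness
    out$fitness <- fitnessLaw(type = ft$type %||% "uniform",
                              min = ft$min %||% 0.35, max = ft$max %||% 1,
                              value = ft$value %||% 0.5)
  }
  if (!is.null(raw$drift)) {
    dr <- raw$drift
    kernArgs <- dr[names(dr) %in% names(formals(driftKernel))]
    out$kernel <- do.call(driftKernel, kernArgs)
    if (!is.null(dr$L1)) out$partition <- toyPartition(dr$L1, dr$L2)
    else if (!is.null(dr$fasta)) {
      seqs <- readFastaAA(dr$fasta)
      out$partition <- partitionFromSequences(seqs[[1]], seqs[[2]])
    }
  }
  out$simulation <- raw$simulation %||% list()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reproducibility manifest for a run
#'
#' Records the resolved configuration, root seed and package version as
#' JSON; the manifest suffices to reproduce the run bit-identically.
#'
#' @param path output JSON path.
#' @param config resolved configuration list (as from
#'   \code{\link{readRunConfig}}; the \code{raw} entry is stored).
#' @param seed root seed used.
#' @param extra optional named list of extra entries.
#' @export
writeRunManifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(
    package = "gcbranch",
    version = as.character(utils::packageVersion("gcbranch")),
    seed = seed,
    config = config$raw %||% config), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
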