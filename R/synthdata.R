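#' Generate a nested survey taxonomy
#'
#' Builds a rooted, fully labelled taxonomy with a nested clade series along
#' the focal path (mirroring the eukaryotic series that ends in the
#' metazoan-like clade) plus basal outgroup clades attached at the root. Each
#' named clade carries `nPerClade` leaf organisms; all branch lengths are
#' `branchLength`. The construction is deterministic; `seed` is accepted for
#' interface uniformity with the other generators.
#'
#' @param nPerClade organisms attached directly to each clade.
#' @param cladeSeries nested clade names, root first.
#' @param outgroups clade names attached as children of the root.
#' @param branchLength branch length for every edge.
#' @param seed unused (deterministic construction).
#' @return A [Taxonomy-class] whose focal path is `cladeSeries`.
#' @export
generateTaxonomy <- function(nPerClade = 2L,
                             cladeSeries = c("LECA", "Obazoa",
                                             "Opisthokonta", "Holozoa",
                                             "Metazoa", "Vertebrata"),
                             outgroups = c("Excavata", "Archaeplastida"),
                             branchLength = 1, seed = 1L) {
  leafNames <- function(clade)
    paste0(tolower(substr(clade, 1L, 4L)), "_", seq_len(nPerClade))
  leaves <- function(clade)
    paste0(leafNames(clade), ":", branchLength, collapse = ",")
  sub <- NULL
  for (k in rev(seq_along(cladeSeries))) {
    clade <- cladeSeries[k]
    inner <- if (is.null(sub)) leaves(clade)
             else paste0(leaves(clade), ",", sub)
    sub <- paste0("(", inner, ")", clade,
                  if (k > 1L) paste0(":", branchLength) else "")
  }
  og <- vapply(outgroups, function(cl)
    paste0("(", leaves(cl), ")", cl, ":", branchLength), "")
  root <- sub
  # splice outgroups into the root clade's child list
  rootInner <- sub("^\\(", "", sub)
  nwk <- paste0("(", paste(og, collapse = ","), ",", rootInner, ";")
  readTaxonomy(text = nwk, focalClade = cladeSeries[length(cladeSeries)])
}

#' Specify a synthetic protein family
#'
#' Describes one planted family: its domain architecture at birth (ordered
#' domains with block lengths), the clade where it is born, per-clade
#' evolutionary events, and its substitution rates. Events are lists with a
#' `type` field:
#' \describe{
#'   \item{domain_gain}{`clade`, `domain`, optional `after` (domain id whose
#'     first occurrence the new block follows; `"start"`/`"end"`).}
#'   \item{domain_loss}{`clade`, `domain` (first occurrence removed).}
#'   \item{motif_plant}{`clade`, `motif` (literal instance), `region`
#'     (`"C_tail"`/`"N_tail"`), optional `offset` (1-based within the tail)
#'     and `copies`.}
#'   \item{region_plant}{`clade`, `region` id from the domain library,
#'     inserted at the start of the C-tail; conserved like a domain but
#'     invisible to the architecture (an activator-region-style element).}
#'   \item{duplication}{`clade`, `count` extra gene copies.}
#'   \item{loss}{`clade`: the family disappears in that subtree.}
#' }
#'
#' @param family family id.
#' @param architecture data.frame with columns `domain`, `length` (ordered).
#' @param birthClade clade where the family appears.
#' @param events list of event lists.
#' @param rate substitutions per site per unit branch length in tails and
#'   linkers.
#' @param domainRateMult rate multiplier inside domain (and region) blocks.
#' @param nTail,cTail,linker block lengths at birth.
#' @param relaxReciprocal,collapseRepeats,motifPolicy survey options carried
#'   to [queryFamily()] / motif statistics.
#' @return A `familySpec` list.
#' @export
familySpec <- function(family, architecture, birthClade, events = list(),
                       rate = 0.1, domainRateMult = 0.5,
                       nTail = 15L, cTail = 60L, linker = 8L,
                       relaxReciprocal = FALSE, collapseRepeats = TRUE,
                       motifPolicy = "C_tail") {
  stopifnot(is.data.frame(architecture),
            all(c("domain", "length") %in% names(architecture)),
            nrow(architecture) >= 1L)
  structure(list(family = family, architecture = architecture,
                 birthClade = birthClade, events = events, rate = rate,
                 domainRateMult = domainRateMult, nTail = nTail,
                 cTail = cTail, linker = linker,
                 relaxReciprocal = relaxReciprocal,
                 collapseRepeats = collapseRepeats,
                 motifPolicy = motifPolicy),
            class = "familySpec")
}

# ---- internal evolution machinery ------------------------------------------

.bgSeq <- function(len, bg) sample.int(20L, len, replace = TRUE,
                                        prob = bg) - 1L

# substitute each site with prob 1 - exp(-dist); replacement uniform over the
# other 19 residues (equal-exchangeability model); X (20) sites never change
.mutateSeq <- function(seq, dist) {
  if (dist <= 0 || !length(seq)) return(seq)
  p <- 1 - exp(-dist)
  hit <- which(stats::runif(length(seq)) < p & seq < 20L)
  if (length(hit))
    seq[hit] <- (seq[hit] + sample.int(19L, length(hit),
                                       replace = TRUE)) %% 20L
  seq
}

.newGene <- function(spec, library, famDivergence, bg) {
  blocks <- list(list(kind = "ntail", domain = NA_character_,
                      seq = .bgSeq(spec$nTail, bg)))
  arch <- spec$architecture
  for (k in seq_len(nrow(arch))) {
    if (k > 1L)
      blocks[[length(blocks) + 1L]] <-
        list(kind = "linker", domain = NA_character_,
             seq = .bgSeq(spec$linker, bg))
    blocks[[length(blocks) + 1L]] <-
      list(kind = "domain", domain = arch$domain[k],
           seq = .mutateSeq(library[[arch$domain[k]]], famDivergence))
  }
  blocks[[length(blocks) + 1L]] <- list(kind = "ctail",
                                        domain = NA_character_,
                                        seq = .bgSeq(spec$cTail, bg))
  list(blocks = blocks)
}

.mutateGene <- function(gene, dist, domainMult) {
  gene$blocks <- lapply(gene$blocks, function(b) {
    d <- if (b$kind %in% c("domain", "region")) dist * domainMult else dist
    b$seq <- .mutateSeq(b$seq, d)
    b
  })
  gene
}

.applyEvent <- function(state, ev, spec, library, famDivergence, bg) {
  if (ev$type == "loss") return(list())
  if (!length(state)) return(state)
  if (ev$type == "duplication") {
    extra <- lapply(seq_len(ev$count), function(i)
      .mutateGene(state[[1L]], 0.05, 1))
    return(c(state, extra))
  }
  state <- lapply(state, function(gene) {
    bl <- gene$blocks
    if (ev$type == "domain_gain") {
      newB <- list(kind = "domain", domain = ev$domain,
                   seq = .mutateSeq(library[[ev$domain]], famDivergence))
      after <- if (is.null(ev$after)) "end" else ev$after
      domIdx <- which(vapply(bl, function(b) b$kind == "domain", TRUE))
      pos <- if (identical(after, "start")) {
        if (length(domIdx)) domIdx[1L] - 1L else 1L
      } else if (identical(after, "end")) {
        if (length(domIdx)) domIdx[length(domIdx)] else length(bl) - 1L
      } else {
        hit <- domIdx[vapply(bl[domIdx], function(b)
          b$domain == after, TRUE)]
        if (!length(hit)) stop("domain_gain after unknown domain: ", after)
        hit[1L]
      }
      gene$blocks <- append(bl, list(newB), after = pos)
    } else if (ev$type == "domain_loss") {
      hit <- which(vapply(bl, function(b)
        b$kind == "domain" && identical(b$domain, ev$domain), TRUE))
      if (length(hit)) gene$blocks <- bl[-hit[1L]]
    } else if (ev$type == "region_plant") {
      newB <- list(kind = "region", domain = ev$region,
                   seq = .mutateSeq(library[[ev$region]], famDivergence))
      ct <- which(vapply(bl, function(b) b$kind == "ctail", TRUE))[1L]
      gene$blocks <- append(bl, list(newB), after = ct - 1L)
    } else if (ev$type == "motif_plant") {
      kind <- if (identical(ev$region, "N_tail")) "ntail" else "ctail"
      t <- which(vapply(bl, function(b) b$kind == kind, TRUE))[1L]
      inst <- aaToInt(ev$motif)
      copies <- if (is.null(ev$copies)) 1L else ev$copies
      off <- if (is.null(ev$offset)) 5L else ev$offset
      s <- bl[[t]]$seq
      for (cpy in seq_len(copies)) {
        at <- off + (cpy - 1L) * (length(inst) + 4L)
        if (at + length(inst) - 1L <= length(s))
          s[at:(at + length(inst) - 1L)] <- inst
      }
      gene$blocks[[t]]$seq <- s
    } else stop("unknown event type: ", ev$type)
    gene
  })
  state
}

.geneSeq <- function(gene)
  intToAa(unlist(lapply(gene$blocks, `[[`, "seq")))

.geneArch <- function(gene) {
  d <- vapply(gene$blocks, function(b)
    if (b$kind == "domain") b$domain else NA_character_, "")
  d[!is.na(d)]
}

# block coordinate table for one gene (1-based inclusive)
.geneBlocks <- function(gene) {
  lens <- vapply(gene$blocks, function(b) length(b$seq), 0L)
  end <- cumsum(lens)
  start <- end - lens + 1L
  data.frame(kind = vapply(gene$blocks, `[[`, "", "kind"),
             domain = vapply(gene$blocks, function(b)
               if (is.null(b$domain) || is.na(b$domain)) NA_character_
               else b$domain, ""),
             start = start, end = end)
}

#' Evolve one family along a taxonomy
#'
#' Simulates the family's genes down the tree: the root gene is assembled at
#' the birth clade from shared domain-library blocks (each diverged by
#' `famDivergence` to individualise the family) and background tails/linkers;
#' along each branch every site substitutes with probability
#' `1 - exp(-rate * branchLength)` (domain/region blocks at
#' `rate * domainRateMult`), replacements drawn uniformly from the other 19
#' residues; events fire at their clade's root. There are no indels inside
#' domain blocks. Deterministic given `seed`.
#'
#' @param spec a [familySpec()].
#' @param tax a [Taxonomy-class].
#' @param library named list, domain/region id -> root block (integer codes),
#'   as built by [generateSurveyFixture()]; generated on the fly if `NULL`.
#' @param seed RNG seed.
#' @param famDivergence divergence applied to library blocks at family birth.
#' @param bg background distribution.
#' @return List with `genes` (organism -> list of gene objects) and
#'   `sequences` (organism -> named character vector).
#' @export
evolveFamily <- function(spec, tax, library = NULL, seed = 1L,
                         famDivergence = 0.25, bg = aaBackground()) {
  evClades <- vapply(spec$events, `[[`, "", "clade")
  known <- names(tax@cladeLeaves)
  bad <- setdiff(c(spec$birthClade, evClades), known)
  if (length(bad)) stop("event references unknown clade: ",
                        paste(bad, collapse = ", "))
  withSeed(seed, {
    if (is.null(library)) {
      ids <- unique(spec$architecture$domain)
      library <- lapply(stats::setNames(spec$architecture$length[
        match(ids, spec$architecture$domain)], ids), .bgSeq, bg = bg)
    }
    tree <- tax@tree
    ntip <- length(tree$tip.label)
    labs <- tree$node.label
    out <- new.env(parent = emptyenv())
    out$genes <- list()
    recurse <- function(node, state) {
      if (node > ntip) {
        clade <- labs[node - ntip]
        if (!is.na(clade) && clade == spec$birthClade && !length(state))
          state <- list(.newGene(spec, library, famDivergence, bg))
        if (!is.na(clade) && length(evClades))
          for (ev in spec$events[evClades == clade])
            state <- .applyEvent(state, ev, spec, library, famDivergence, bg)
        kids <- which(tree$edge[, 1] == node)
        for (e in kids) {
          child <- tree$edge[e, 2]
          len <- if (is.null(tree$edge.length)) 1 else tree$edge.length[e]
          childState <- lapply(state, .mutateGene, dist = spec$rate * len,
                               domainMult = spec$domainRateMult)
          recurse(child, childState)
        }
      } else {
        out$genes[[tree$tip.label[node]]] <- state
      }
    }
    recurse(ntip + 1L, list())
    genes <- out$genes[tree$tip.label]
    seqs <- lapply(stats::setNames(names(genes), names(genes)), function(o) {
      g <- genes[[o]]
      if (!length(g)) return(character())
      stats::setNames(vapply(g, .geneSeq, ""),
                      paste0(o, "_", spec$family,
                             ifelse(seq_along(g) == 1L, "",
                                    paste0("_c", seq_along(g)))))
    })
    list(genes = genes, sequences = seqs)
  })
}

# independent epoch computation from a planted presence set (set logic on the
# clade series; used for the truth table)
.truthEpoch <- function(presentOrgs, tax) {
  if (!length(presentOrgs)) return("not_found")
  for (clade in rev(tax@focalPath))
    if (all(presentOrgs %in% tax@cladeLeaves[[clade]])) return(clade)
  tax@focalPath[1L]
}

#' The default planted family set
#'
#' Eight families emulating the canonical emergence scenarios of the animal
#' endocytic machinery: ancient (root) families, an opisthokont gain, a
#' holozoan family whose earlier relatives lack one domain (the
#' dynamin/DRP-style partial-architecture ancestor), a tandem-repeat
#' expansion, a vertebrate-specific duplication, motif gains, and an
#' activator-region (APA-style) gain in holozoan FCHO-like proteins. Domains
#' are drawn from a shared library, so families sharing a domain (e.g. the
#' mu-homology domain) are realistically related.
#'
#' @return Named list of [familySpec()]s.
#' @export
defaultFamilySpecs <- function() {
  arch <- function(...) {
    x <- c(...)
    data.frame(domain = names(x), length = unname(x))
  }
  list(
    CLTC = familySpec("CLTC", arch(CLH_N = 60L, CLH_R = 60L), "LECA"),
    AP2M = familySpec("AP2M", arch(LONGIN = 45L, MUHD = 60L), "LECA"),
    FCHO = familySpec("FCHO", arch(FBAR = 60L, MUHD = 60L), "Opisthokonta",
      events = list(list(type = "region_plant", clade = "Holozoa",
                         region = "APA"))),
    DNM = familySpec("DNM", arch(GTPASE = 70L), "LECA",
      events = list(list(type = "domain_gain", clade = "Holozoa",
                         domain = "PH", after = "GTPASE"))),
    ITSN = familySpec("ITSN",
      data.frame(domain = c("EH", "EH", "CC", "SH3", "SH3"),
                 length = c(45L, 45L, 40L, 45L, 45L)), "Holozoa",
      events = list(list(type = "domain_gain", clade = "Metazoa",
                         domain = "SH3", after = "end"),
                    list(type = "domain_gain", clade = "Metazoa",
                         domain = "SH3", after = "end"),
                    list(type = "domain_gain", clade = "Metazoa",
                         domain = "SH3", after = "end"))),
    CALM = familySpec("CALM", arch(ANTH = 75L), "LECA",
      events = list(list(type = "motif_plant", clade = "LECA",
                         motif = "NPF", region = "C_tail", copies = 2L),
                    list(type = "duplication", clade = "Vertebrata",
                         count = 2L))),
    EPS15 = familySpec("EPS15",
      data.frame(domain = c("EH", "EH", "CC"),
                 length = c(45L, 45L, 40L)), "Obazoa",
      events = list(list(type = "motif_plant", clade = "Metazoa",
                         motif = "DPW", region = "C_tail", copies = 2L))),
    STON = familySpec("STON", arch(SHD = 45L, MUHD = 60L), "Metazoa",
      events = list(list(type = "motif_plant", clade = "Metazoa",
                         motif = "DPF", region = "N_tail")),
      motifPolicy = "N_tail"))
}

#' Generate a complete survey fixture with planted truth
#'
#' Builds the full synthetic input set for an end-to-end survey: a shared
#' domain library, every family evolved along the taxonomy, per-organism
#' proteomes (family genes plus `nDecoys` background decoy sequences), seed
#' alignments from the four model-organism leaves (the two metazoan and two
#' vertebrate organisms, ungapped by construction), per-domain seed
#' alignments, an activator-region (APA-style) seed from three model
#' organisms, and the truth table recording, per family and organism, the
#' expected call status, paralog count, per-pattern motif counts in the true
#' tails, and the expected emergence epoch.
#'
#' @param specs named list of [familySpec()]s.
#' @param tax a [Taxonomy-class]; default [generateTaxonomy()].
#' @param nDecoys background decoy sequences per proteome.
#' @param decoyLenRange decoy length range.
#' @param seed master RNG seed.
#' @param dir optional directory: when given, proteomes/seeds/domains/
#'   taxonomy/truth are also written as FASTA/Newick/TSV files.
#' @return List with `taxonomy`, `proteomes` (named list of
#'   [Proteome-class]), `families` (named list of [queryFamily()]),
#'   `seedAlignments`, `domainAlignments`, `apaSeed`, `refOrganism`,
#'   `modelOrganisms`, `truth` (data.frame) and `truthEpochs`.
#' @export
generateSurveyFixture <- function(specs = defaultFamilySpecs(), tax = NULL,
                                  nDecoys = 200L,
                                  decoyLenRange = c(80L, 300L),
                                  seed = 42L, dir = NULL) {
  if (is.null(tax)) tax <- generateTaxonomy()
  bg <- aaBackground()
  orgs <- tax@tree$tip.label
  focal <- tax@focalPath[length(tax@focalPath)]        # e.g. Vertebrata
  penult <- tax@focalPath[length(tax@focalPath) - 1L]  # e.g. Metazoa
  modelOrgs <- c(setdiff(tax@cladeLeaves[[penult]],
                         tax@cladeLeaves[[focal]]),
                 tax@cladeLeaves[[focal]])
  refOrganism <- tax@cladeLeaves[[focal]][1L]

  # shared domain/region library
  allArch <- do.call(rbind, lapply(specs, function(s) s$architecture))
  gains <- do.call(rbind, lapply(specs, function(s) {
    rows <- lapply(s$events, function(ev) {
      if (ev$type == "domain_gain")
        data.frame(domain = ev$domain, length = 45L)
      else if (ev$type == "region_plant")
        data.frame(domain = ev$region, length = 25L)
      else NULL
    })
    do.call(rbind, rows)
  }))
  allArch <- rbind(allArch, gains)
  ids <- unique(allArch$domain)
  library <- withSeed(deriveSeed(seed, "library"), {
    lapply(stats::setNames(allArch$length[match(ids, allArch$domain)], ids),
           .bgSeq, bg = bg)
  })

  fams <- lapply(specs, function(s)
    evolveFamily(s, tax, library = library,
                 seed = deriveSeed(seed, paste0("fam_", s$family)), bg = bg))
  names(fams) <- names(specs)

  # proteomes: family genes + decoys
  proteomes <- list()
  for (o in orgs) {
    seqs <- unlist(unname(lapply(fams, function(f) f$sequences[[o]])))
    if (is.null(seqs)) seqs <- character()
    decoys <- withSeed(deriveSeed(seed, paste0("decoy_", o)), {
      lens <- sample(decoyLenRange[1]:decoyLenRange[2], nDecoys,
                     replace = TRUE)
      stats::setNames(vapply(lens, function(L) intToAa(.bgSeq(L, bg)), ""),
                      sprintf("%s_decoy_%03d", o, seq_len(nDecoys)))
    })
    proteomes[[o]] <- Proteome(o, c(seqs, decoys),
                               taxonPath = organismPath(tax, o))
  }

  # seed alignments from the model organisms (primary gene copies)
  seedAlignments <- list()
  for (fn in names(specs)) {
    rows <- list()
    for (o in modelOrgs) {
      g <- fams[[fn]]$genes[[o]]
      if (length(g)) rows[[paste0(o, "_", fn)]] <- .geneSeq(g[[1L]])
    }
    if (length(rows) < 2L)
      stop("family ", fn, " lacks model-organism members for its seed")
    lens <- unique(nchar(unlist(rows)))
    if (length(lens) != 1L)
      stop("model-organism genes of ", fn, " are not equal length")
    seedAlignments[[fn]] <- SeedAlignment(unlist(rows), id = fn)
  }

  # per-domain alignments from model-organism instances
  domainAlignments <- list()
  for (d in setdiff(ids, "APA")) {
    rows <- list()
    for (fn in names(specs)) for (o in modelOrgs) {
      g <- fams[[fn]]$genes[[o]]
      if (!length(g)) next
      bl <- g[[1L]]$blocks
      hit <- which(vapply(bl, function(b)
        b$kind == "domain" && identical(b$domain, d), TRUE))
      for (h in seq_along(hit))
        rows[[paste0(o, "_", fn, "_", d, h)]] <- intToAa(bl[[hit[h]]]$seq)
    }
    if (length(rows) >= 2L)
      domainAlignments[[d]] <- SeedAlignment(unlist(rows), id = d)
  }

  # activator-region seed from three model organisms (synthetic APA)
  apaSeed <- NULL
  if ("APA" %in% ids) {
    rows <- list()
    for (o in modelOrgs[c(1L, 2L, 3L)]) {
      for (fn in names(specs)) {
        g <- fams[[fn]]$genes[[o]]
        if (!length(g)) next
        bl <- g[[1L]]$blocks
        hit <- which(vapply(bl, function(b)
          b$kind == "region" && identical(b$domain, "APA"), TRUE))
        if (length(hit))
          rows[[paste0(o, "_", fn, "_APA")]] <- intToAa(bl[[hit[1L]]]$seq)
      }
    }
    if (length(rows) >= 2L) apaSeed <- SeedAlignment(unlist(rows), id = "APA")
  }

  # query-family table keyed to the reference organism's architectures
  families <- list()
  for (fn in names(specs)) {
    gRef <- fams[[fn]]$genes[[refOrganism]]
    if (!length(gRef)) stop("family ", fn, " absent from reference organism")
    refArch <- .geneArch(gRef[[1L]])
    designated <- names(fams[[fn]]$sequences[[refOrganism]])
    families[[fn]] <- queryFamily(fn, refArch, designated,
                                  relaxReciprocal =
                                    specs[[fn]]$relaxReciprocal,
                                  collapseRepeats =
                                    specs[[fn]]$collapseRepeats)
  }

  # truth table
  registry <- motifRegistry()
  truthRows <- list()
  for (fn in names(specs)) {
    refArchC <- collapseRuns(.geneArch(fams[[fn]]$genes[[refOrganism]][[1L]]))
    for (o in orgs) {
      g <- fams[[fn]]$genes[[o]]
      full <- vapply(g, function(gn)
        identical(collapseRuns(.geneArch(gn)), refArchC), TRUE)
      shares <- vapply(g, function(gn)
        length(intersect(.geneArch(gn), refArchC)) > 0L, TRUE)
      status <- if (any(full)) "homolog"
                else if (any(shares)) "analog_ancestor" else "absent"
      mc <- vapply(names(registry), function(pn) {
        pol <- if (pn %in% c("AP2", "clathrin", "EH") &&
                   specs[[fn]]$motifPolicy == "N_tail") "ntail" else "ctail"
        cnt <- 0L
        for (gn in g[full]) {
          blk <- .geneBlocks(gn)
          tl <- blk[blk$kind == pol, , drop = FALSE]
          if (!nrow(tl)) next
          s <- .geneSeq(gn)
          reg <- substr(s, tl$start[1L], tl$end[nrow(tl)])
          cnt <- cnt + scanMotif(reg, registry[[pn]])$count
        }
        cnt
      }, 0L)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        family = fn, organism = o, status = status,
        paralogs = if (status == "homolog") sum(full) else 0L,
        AP2 = mc[["AP2"]], clathrin = mc[["clathrin"]], EH = mc[["EH"]])
    }
  }
  truth <- do.call(rbind, truthRows)
  truthEpochs <- vapply(names(specs), function(fn) {
    pres <- truth$organism[truth$family == fn & truth$status == "homolog"]
    .truthEpoch(pres, tax)
  }, "")

  fixture <- list(taxonomy = tax, proteomes = proteomes,
                  families = families, seedAlignments = seedAlignments,
                  domainAlignments = domainAlignments, apaSeed = apaSeed,
                  refOrganism = refOrganism, modelOrganisms = modelOrgs,
                  truth = truth, truthEpochs = truthEpochs, seed = seed)
  if (!is.null(dir)) writeFixture(fixture, dir)
  fixture
}

#' Write a survey fixture to disk
#'
#' Layout: `proteomes/*.fasta`, `seeds/*.afa`, `domains/*.afa`,
#' `taxonomy.nwk`, `truth.tsv`.
#'
#' @param fixture result of [generateSurveyFixture()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  for (d in file.path(dir, c("proteomes", "seeds", "domains")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (o in names(fixture$proteomes))
    writeProteome(fixture$proteomes[[o]],
                  file.path(dir, "proteomes", paste0(o, ".fasta")))
  writeAln <- function(aln, path)
    Biostrings::writeXStringSet(sequences(aln), path)
  for (fn in names(fixture$seedAlignments))
    writeAln(fixture$seedAlignments[[fn]],
             file.path(dir, "seeds", paste0(fn, ".afa")))
  for (d in names(fixture$domainAlignments))
    writeAln(fixture$domainAlignments[[d]],
             file.path(dir, "domains", paste0(d, ".afa")))
  if (!is.null(fixture$apaSeed))
    writeAln(fixture$apaSeed, file.path(dir, "seeds", "APA.afa"))
  ape::write.tree(fixture$taxonomy@tree, file.path(dir, "taxonomy.nwk"))
  writeTsvAtomic(fixture$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Generate synthetic interaction records with planted truth
#'
#' Emits one whitelist-method record per true edge and `nNoise` noise records
#' carrying blacklisted methods (random node pairs), so that evidence
#' filtering must recover exactly the truth graph. Deterministic given
#' `seed`.
#'
#' @param trueEdges data.frame with columns `a`, `b`.
#' @param nodes node universe for noise pairs (default: nodes of
#'   `trueEdges`).
#' @param nNoise number of blacklist-method noise records.
#' @param seed RNG seed.
#' @param path optional output file (PSI-MI TAB 2.5-like, 15 columns).
#' @return data.frame of records as [readInteractions()] would return them.
#' @export
generateInteractions <- function(trueEdges, nodes = NULL, nNoise = 10L,
                                 seed = 1L, path = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(trueEdges$a, trueEdges$b)))
  white <- c("affinity chromatography technology (affinity purification)",
             "reconstituted complex", "far western blotting",
             "protein-fragment complementation assay", "biochemical activity")
  black <- c("two-hybrid screening", "colocalization by fluorescence",
             "cofractionation", "high throughput two-hybrid")
  recs <- withSeed(seed, {
    wm <- sample(white, nrow(trueEdges), replace = TRUE)
    out <- data.frame(proteinA = as.character(trueEdges$a),
                      proteinB = as.character(trueEdges$b),
                      method = wm,
                      sourceDb = rep("synthdb", nrow(trueEdges)))
    if (nNoise > 0L) {
      na <- sample(nodes, nNoise, replace = TRUE)
      nb <- sample(nodes, nNoise, replace = TRUE)
      out <- rbind(out, data.frame(
        proteinA = na, proteinB = nb,
        method = sample(black, nNoise, replace = TRUE),
        sourceDb = "synthdb"))
    }
    out
  })
  recs$selfLoop <- recs$proteinA == recs$proteinB
  if (!is.null(path)) {
    tab <- cbind(recs$proteinA, recs$proteinB, "-", "-", "-", "-",
                 recs$method, "-", "-", "-", "-", "-", recs$sourceDb,
                 "-", "-")
    lines <- c(paste0("#ID(A)\tID(B)\tAltID(A)\tAltID(B)\tAlias(A)\t",
                      "Alias(B)\tMethod\tAuthor\tPubID\tTaxA\tTaxB\t",
                      "Type\tSourceDB\tIntID\tConf"),
               apply(tab, 1L, paste, collapse = "\t"))
    writeLines(lines, path)
  }
  recs
}
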