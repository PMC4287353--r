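#' Configuration for the synthetic multi-domain family generator
#'
#' Describes a dataset of protein families built from reusable domain
#' blocks. Each domain type gets one random master sequence; each family is
#' defined by an ordered architecture of domain types; each member is the
#' concatenation of its family's masters with i.i.d. point substitutions. A
#' fraction of members have their domain order shuffled and a fraction are
#' circularly permuted, emulating the rearrangements that defeat
#' alignment-based comparison. The defaults describe three families of eight
#' members each, sharing one promiscuous domain type, with a 5% per-residue
#' substitution rate and a quarter of each family domain-shuffled.
#'
#' @param n_families Number of families.
#' @param members_per_family Members generated per family.
#' @param architectures Optional list of domain-identifier vectors, one per
#'   family. When `NULL`, default architectures are built: family `i` uses
#'   three private types plus one type `Dsh` shared by all families.
#' @param domain_length_range Length-2 integer vector, min/max residues per
#'   domain master (uniform); must be >= 5 so fragments exist.
#' @param substitution_rate Per-residue probability of a point substitution;
#'   replacements are drawn uniformly from the other 19 residues.
#' @param shuffle_fraction Fraction of each family's members whose domain
#'   order is randomly permuted (guaranteed different from the original when
#'   the architecture has more than one domain).
#' @param circular_permute_fraction Fraction of each family's members whose
#'   domain list is circularly rotated (drawn from members not shuffled).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_families = 3L,
                         members_per_family = 8L,
                         architectures = NULL,
                         domain_length_range = c(30L, 60L),
                         substitution_rate = 0.05,
                         shuffle_fraction = 0.25,
                         circular_permute_fraction = 0,
                         seed = 1L) {
  if (is.null(architectures)) {
    architectures <- lapply(seq_len(n_families), function(i) {
      c(paste0("D", i, letters[1:3]), "Dsh")
    })
  }
  if (length(architectures) != n_families) {
    stop("need one architecture per family", call. = FALSE)
  }
  stopifnot(
    n_families >= 1L, members_per_family >= 1L,
    length(domain_length_range) == 2L,
    domain_length_range[1L] >= 5L,
    domain_length_range[2L] >= domain_length_range[1L],
    substitution_rate >= 0, substitution_rate <= 1,
    shuffle_fraction >= 0, shuffle_fraction <= 1,
    circular_permute_fraction >= 0, circular_permute_fraction <= 1,
    shuffle_fraction + circular_permute_fraction <= 1
  )
  structure(
    list(n_families = as.integer(n_families),
         members_per_family = as.integer(members_per_family),
         architectures = lapply(architectures, as.character),
         domain_types = unique(unlist(architectures)),
         domain_length_range = as.integer(domain_length_range),
         substitution_rate = substitution_rate,
         shuffle_fraction = shuffle_fraction,
         circular_permute_fraction = circular_permute_fraction,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic multi-domain protein dataset
#'
#' @param cfg A [synth_config()].
#' @return A list with `records` (named [Biostrings::AAStringSet]), `archs`
#'   (named list of per-protein domain vectors, reflecting any shuffling or
#'   permutation), `truth` (named integer vector of family indices) and
#'   `masters` (named character vector of domain master sequences).
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(seed = 42))
#' length(ds$records)  # 24
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  lens <- sample(cfg$domain_length_range[1L]:cfg$domain_length_range[2L],
                 length(cfg$domain_types), replace = TRUE)
  masters <- vapply(lens, function(L) {
    paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
  }, character(1))
  names(masters) <- cfg$domain_types

  records <- character(0)
  archs <- list()
  truth <- integer(0)
  m <- cfg$members_per_family
  n_shuf <- round(cfg$shuffle_fraction * m)
  n_circ <- round(cfg$circular_permute_fraction * m)
  for (fam in seq_len(cfg$n_families)) {
    base_arch <- cfg$architectures[[fam]]
    rearranged <- if (n_shuf + n_circ > 0L) {
      sample(m, n_shuf + n_circ)
    } else {
      integer(0)
    }
    shuffled <- rearranged[seq_len(n_shuf)]
    circular <- setdiff(rearranged, shuffled)
    for (mem in seq_len(m)) {
      arch <- base_arch
      if (mem %in% shuffled && length(arch) > 1L) {
        repeat {
          perm <- sample(length(arch))
          if (!identical(perm, seq_along(arch))) break
        }
        arch <- arch[perm]
      } else if (mem %in% circular && length(arch) > 1L) {
        rot <- sample(length(arch) - 1L, 1L)
        arch <- c(arch[(rot + 1L):length(arch)], arch[seq_len(rot)])
      }
      seq <- paste(masters[arch], collapse = "")
      seq <- mutate_sequence(seq, cfg$substitution_rate)
      id <- sprintf("F%d_M%02d", fam, mem)
      records[id] <- seq
      archs[[id]] <- arch
      truth[id] <- fam
    }
  }
  list(records = as_aa_set(records), archs = archs, truth = truth,
       masters = masters)
}

# i.i.d. point substitutions; replacement drawn uniformly from the 19 other
# standard residues.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Write a synthetic dataset to disk
#'
#' Emits the FASTA sequence file, the tab-delimited architecture file and a
#' two-column truth-label TSV (`protein_id TAB family_index`).
#'
#' @param dataset List from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             archs = file.path(dir, "architectures.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(dataset$records, paths[["fasta"]])
  write_architectures(dataset$archs, paths[["archs"]])
  writeLines(paste(names(dataset$truth), dataset$truth, sep = "\t"),
             paths[["truth"]])
  invisible(paths)
}
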