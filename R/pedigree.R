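#' Validate and renumber a pedigree
#'
#' Checks a raw pedigree table for duplicate ids, cycles and sex-inconsistent
#' parent assignments, inserts unlisted parents as founders (unless
#' \code{strict = TRUE}), topologically sorts it so that every parent precedes
#' its offspring, and re-indexes animals \code{1..n}. The missing-parent
#' sentinel in the returned table is \code{0}.
#'
#' @param raw data.frame with columns \code{animal}, \code{sire}, \code{dam}
#'   and optionally \code{sex} (\code{"M"}/\code{"F"} or \code{NA}) and
#'   \code{coat}. Missing parents may be encoded as \code{NA}, \code{0} or
#'   \code{""}.
#' @param strict if \code{TRUE}, a parent id absent from the animal column is
#'   an error instead of being auto-inserted as a founder.
#' @return A \code{pedigree_table}: data.frame with integer columns \code{id},
#'   \code{sire}, \code{dam} (0 = unknown), \code{sex}, \code{coat},
#'   \code{gen} (generation index, founders 0) and \code{label} (original id).
#' @export
validate_and_renumber <- function(raw, strict = FALSE) {
  stopifnot(is.data.frame(raw), all(c("animal", "sire", "dam") %in% names(raw)))
  norm_id <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  animal <- norm_id(raw$animal)
  sire <- norm_id(raw$sire)
  dam <- norm_id(raw$dam)
  if (anyNA(animal)) stop("missing animal id in pedigree row(s) ",
                          paste(which(is.na(animal)), collapse = ", "))
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  sex <- if ("sex" %in% names(raw)) as.character(raw$sex) else rep(NA_character_, length(animal))
  coat <- if ("coat" %in% names(raw)) as.character(raw$coat) else rep(NA_character_, length(animal))
  coat[!is.na(coat) & coat == "unknown"] <- NA_character_

  # auto-insert parents that never appear as animals
  extra <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(extra)) {
    if (strict) stop("parent id(s) absent from pedigree: ",
                     paste(extra, collapse = ", "))
    warning(length(extra), " parent id(s) not listed as animals; inserted as founders")
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    sex <- c(sex, rep(NA_character_, length(extra)))
    coat <- c(coat, rep(NA_character_, length(extra)))
  }
  n <- length(animal)
  si <- match(sire, animal)   # NA = unknown
  di <- match(dam, animal)
  if (any(!is.na(si) & si == seq_len(n)) || any(!is.na(di) & di == seq_len(n)))
    stop("animal listed as its own parent: ",
         animal[which(si == seq_len(n) | di == seq_len(n))[1]])

  # sex consistency: an animal used as sire must not be recorded female, etc.
  as_sire <- unique(stats::na.omit(si))
  as_dam <- unique(stats::na.omit(di))
  bad <- intersect(as_sire, as_dam)
  if (length(bad)) stop("animal used as both sire and dam: ", animal[bad[1]])
  if (any(sex[as_sire] %in% "F")) stop("female animal used as sire: ",
                                       animal[as_sire[sex[as_sire] %in% "F"][1]])
  if (any(sex[as_dam] %in% "M")) stop("male animal used as dam: ",
                                      animal[as_dam[sex[as_dam] %in% "M"][1]])
  sex[is.na(sex) & seq_len(n) %in% as_sire] <- "M"
  sex[is.na(sex) & seq_len(n) %in% as_dam] <- "F"

  # Kahn topological sort; generation = 1 + max(parent generations)
  npar <- (!is.na(si)) + (!is.na(di))
  kids <- split(rep(seq_len(n), 2)[!is.na(c(si, di))],
                c(si, di)[!is.na(c(si, di))])
  gen <- integer(n)
  order_out <- integer(n)
  queue <- which(npar == 0L)
  done <- 0L
  remaining <- npar
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    done <- done + 1L
    order_out[done] <- i
    for (k in kids[[as.character(i)]]) {
      remaining[k] <- remaining[k] - 1L
      gen[k] <- max(gen[k], gen[i] + 1L)
      if (remaining[k] == 0L) queue <- c(queue, k)
    }
  }
  if (done < n)
    stop("pedigree cycle detected involving animal(s): ",
         paste(animal[remaining > 0L][seq_len(min(5L, sum(remaining > 0L)))],
               collapse = ", "))
  ord <- order_out
  newpos <- integer(n); newpos[ord] <- seq_len(n)
  out <- data.frame(
    id = seq_len(n),
    sire = ifelse(is.na(si[ord]), 0L, newpos[si[ord]]),
    dam = ifelse(is.na(di[ord]), 0L, newpos[di[ord]]),
    sex = sex[ord],
    coat = coat[ord],
    gen = gen[ord],
    label = animal[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("pedigree_table", "data.frame")
  out
}

#' @export
print.pedigree_table <- function(x, n = 6L, ...) {
  cat("Pedigree:", nrow(x), "animals,",
      sum(x$sire == 0L & x$dam == 0L), "founders, max generation",
      max(x$gen), "\n")
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("# ...", nrow(x) - n, "more animals\n")
  invisible(x)
}

is_pedigree_table <- function(x) inherits(x, "pedigree_table")

#' Trace ancestors of focal animals
#'
#' Restricts a pedigree to a set of focal animals plus all their ancestors
#' within \code{max_generations} meioses. Parents beyond the horizon become
#' unknown.
#'
#' @param ped a \code{pedigree_table}.
#' @param focal_ids integer ids (renumbered) of the focal animals.
#' @param max_generations non-negative integer ancestor horizon.
#' @return A renumbered \code{pedigree_table} for the retained animals.
#' @export
trace_ancestors <- function(ped, focal_ids, max_generations) {
  stopifnot(is_pedigree_table(ped), max_generations >= 0)
  if (!all(focal_ids %in% ped$id)) stop("focal id(s) not in pedigree")
  depth <- rep(Inf, nrow(ped))
  depth[focal_ids] <- 0
  frontier <- focal_ids
  d <- 0
  while (length(frontier) && d < max_generations) {
    par <- unique(c(ped$sire[frontier], ped$dam[frontier]))
    par <- par[par > 0L]
    newly <- par[depth[par] > d + 1]
    depth[newly] <- d + 1
    frontier <- newly
    d <- d + 1
  }
  keep <- which(is.finite(depth))
  sub <- ped[keep, , drop = FALSE]
  # sever parent links that fall outside the horizon
  sub$sire[!(sub$sire %in% keep)] <- 0L
  sub$dam[!(sub$dam %in% keep)] <- 0L
  lab0 <- c(NA_character_, ped$label)
  raw <- data.frame(animal = sub$label,
                    sire = lab0[sub$sire + 1L],
                    dam = lab0[sub$dam + 1L],
                    sex = sub$sex, coat = sub$coat,
                    stringsAsFactors = FALSE)
  validate_and_renumber(raw)
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F from a renumbered pedigree
#' by accumulating the L-row of each animal over its ancestor set, using the
#' within-family (mendelian sampling) variances
#' \eqn{d_j = 0.5 - 0.25 (F_s + F_d)} with the convention \eqn{F = -1} for an
#' unknown parent.
#'
#' @param ped a \code{pedigree_table}.
#' @return Numeric vector of inbreeding coefficients, one per animal.
#' @export
inbreeding_ml <- function(ped) {
  stopifnot(is_pedigree_table(ped))
  n <- nrow(ped)
  sire <- ped$sire; dam <- ped$dam
  F <- numeric(n)
  Fpar <- function(p) if (p == 0L) -1 else F[p]
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (s == 0L || d == 0L) { F[i] <- 0; next }  # F needs both parents
    todo <- i
    L[i] <- 1
    acc <- -1  # a_ii = sum L_j^2 d_j; F_i = a_ii - 1
    touched <- i
    while (length(todo)) {
      j <- max(todo)
      todo <- todo[todo != j]
      sj <- sire[j]; dj <- dam[j]
      if (sj > 0L) {
        if (L[sj] == 0 && !(sj %in% todo)) { todo <- c(todo, sj); touched <- c(touched, sj) }
        L[sj] <- L[sj] + 0.5 * L[j]
      }
      if (dj > 0L) {
        if (L[dj] == 0 && !(dj %in% todo)) { todo <- c(todo, dj); touched <- c(touched, dj) }
        L[dj] <- L[dj] + 0.5 * L[j]
      }
      acc <- acc + L[j]^2 * (0.5 - 0.25 * (Fpar(sj) + Fpar(dj)))
      L[j] <- 0  # j is max of the active set, so its L is final; reset for reuse
    }
    L[touched] <- 0
    F[i] <- acc
  }
  F
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A by the tabular method:
#' \eqn{a_{ii} = 1 + a_{sd}/2} and \eqn{a_{ij} = (a_{js} + a_{jd})/2} for
#' \eqn{j < i}. Intended for small-to-moderate pedigrees; use
#' \code{\link{a_inverse}} for the sparse inverse on large ones.
#'
#' @param ped a \code{pedigree_table}.
#' @param max_n guard against accidental huge dense allocations.
#' @return List with \code{a_matrix} (dense symmetric matrix) and
#'   \code{inbreeding} (\code{diag(A) - 1}).
#' @export
additive_relationship_matrix <- function(ped, max_n = 5000L) {
  stopifnot(is_pedigree_table(ped))
  n <- nrow(ped)
  if (n > max_n) stop("dense A requested for ", n, " animals (max_n = ", max_n, ")")
  A <- matrix(0, n, n)
  sire <- ped$sire; dam <- ped$dam
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (s > 0L) A[s, j] else numeric(i - 1L)
      rd <- if (d > 0L) A[d, j] else numeric(i - 1L)
      A[i, j] <- 0.5 * (rs + rd)
      A[j, i] <- A[i, j]
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  list(a_matrix = A, inbreeding = diag(A) - 1)
}

# Per-animal inverse mendelian-sampling variances (alpha = 1/d_i) used by the
# Henderson A-inverse rules; d depends on how many parents are known and on
# the known parents' inbreeding.
mendelian_alpha <- function(ped, F) {
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], NA)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], NA)
  dvar <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
          ifelse(s > 0L, 0.75 - 0.25 * Fs,
          ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
  1 / dvar
}

# Assemble the sparse inverse from parent-slot indices (0 = absent slot) and
# per-animal alpha. Used both for the plain inverse and the group-augmented
# one (group equations occupy indices n+1 .. n+g).
assemble_ainv <- function(n_eq, animal, slot1, slot2, alpha) {
  ii <- animal; jj <- animal; xx <- alpha
  for (sl in list(slot1, slot2)) {
    has <- sl > 0L
    ii <- c(ii, animal[has], sl[has])
    jj <- c(jj, sl[has], animal[has])
    xx <- c(xx, rep(-alpha[has] / 2, 2))
  }
  h1 <- slot1 > 0L; h2 <- slot2 > 0L
  ii <- c(ii, slot1[h1], slot2[h2], slot1[h1 & h2], slot2[h1 & h2])
  jj <- c(jj, slot1[h1], slot2[h2], slot2[h1 & h2], slot1[h1 & h2])
  xx <- c(xx, alpha[h1] / 4, alpha[h2] / 4, rep(alpha[h1 & h2] / 4, 2))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_eq, n_eq),
                       symmetric = FALSE) |> Matrix::forceSymmetric()
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by the per-animal rules,
#' with mendelian-sampling variances adjusted for parental inbreeding
#' (Meuwissen-Luo coefficients). Matches the dense inverse of the tabular A.
#'
#' @param ped a \code{pedigree_table}.
#' @return List with \code{a_inverse} (sparse symmetric Matrix) and
#'   \code{inbreeding}.
#' @export
a_inverse <- function(ped) {
  stopifnot(is_pedigree_table(ped))
  F <- inbreeding_ml(ped)
  alpha <- mendelian_alpha(ped, F)
  Ainv <- assemble_ainv(nrow(ped), ped$id, ped$sire, ped$dam, alpha)
  list(a_inverse = Ainv, inbreeding = F)
}

#' Assign unknown-parent genetic groups by ancestor coat color
#'
#' Every missing parent slot of the pedigree is assigned to one of five
#' genetic groups keyed by coat color (chestnut, bay, black, gray, unknown).
#' The grouping coat is the recorded coat of the animal carrying the missing
#' slot (that animal is the most-ancestral known individual of the founder
#' line on that side); an unrecorded coat maps to the "unknown" group.
#' Animals with both parents known receive no slots.
#'
#' @param ped a \code{pedigree_table}.
#' @return A \code{genetic_groups} list with \code{labels} (group order) and
#'   \code{slots} (data.frame: animal, slot, group index).
#' @export
assign_genetic_groups <- function(ped) {
  stopifnot(is_pedigree_table(ped))
  labels <- c("chestnut", "bay", "black", "gray", "unknown")
  own <- ifelse(is.na(ped$coat) | !(ped$coat %in% labels), "unknown", ped$coat)
  gidx <- match(own, labels)
  slots <- rbind(
    data.frame(animal = ped$id[ped$sire == 0L], slot = "sire",
               group = gidx[ped$sire == 0L]),
    data.frame(animal = ped$id[ped$dam == 0L], slot = "dam",
               group = gidx[ped$dam == 0L])
  )
  slots <- slots[order(slots$animal, slots$slot), , drop = FALSE]
  rownames(slots) <- NULL
  structure(list(labels = labels, slots = slots), class = "genetic_groups")
}

#' Group-augmented A-inverse (phantom-parent construction)
#'
#' Extends the sparse A-inverse with one equation per genetic group following
#' the Quaas-Pollak/Westell phantom-parent rules: each unknown parent slot is
#' replaced by its group's equation in the per-animal contributions, while
#' mendelian-sampling variances keep the plain unknown-parent values (phantom
#' parents are non-informative founders). On a pedigree with no missing
#' parents the group rows and columns are all zero.
#'
#' @param ped a \code{pedigree_table}.
#' @param groups a \code{genetic_groups} assignment from
#'   \code{\link{assign_genetic_groups}}.
#' @return List with \code{a_inverse} (sparse, dimension n + n_groups; animal
#'   equations first, groups last in \code{groups$labels} order),
#'   \code{inbreeding}, \code{labels}, \code{n_animals}.
#' @export
a_inverse_with_groups <- function(ped, groups = assign_genetic_groups(ped)) {
  stopifnot(is_pedigree_table(ped), inherits(groups, "genetic_groups"))
  n <- nrow(ped)
  g <- length(groups$labels)
  F <- inbreeding_ml(ped)
  alpha <- mendelian_alpha(ped, F)
  slot_of <- function(which_slot, parent) {
    out <- parent
    sl <- groups$slots[groups$slots$slot == which_slot, , drop = FALSE]
    out[sl$animal] <- n + sl$group
    out
  }
  s1 <- slot_of("sire", ped$sire)
  s2 <- slot_of("dam", ped$dam)
  Ainv <- assemble_ainv(n + g, ped$id, s1, s2, alpha)
  list(a_inverse = Ainv, inbreeding = F, labels = groups$labels, n_animals = n)
}

#' Gene-dropping Monte Carlo kinship
#'
#' Drops two distinct alleles per founder through the pedigree and estimates
#' additive relationships as twice the probability that alleles sampled from
#' two animals are identical by descent. Used as an independent check of the
#' tabular A.
#'
#' @param ped a \code{pedigree_table}.
#' @param n_rep number of replicate gene drops.
#' @param pairs 2-column matrix of animal id pairs to estimate.
#' @return data.frame with \code{i}, \code{j}, estimated \code{a} and its
#'   Monte-Carlo standard error.
#' @export
gene_drop_relationship <- function(ped, pairs, n_rep = 20000L) {
  stopifnot(is_pedigree_table(ped))
  n <- nrow(ped)
  al1 <- matrix(0L, n_rep, n)
  al2 <- matrix(0L, n_rep, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (s == 0L) {
      al_s <- rep(next_allele, n_rep); next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      al_s <- ifelse(pick, al1[, s], al2[, s])
    }
    if (d == 0L) {
      al_d <- rep(next_allele, n_rep); next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_rep) < 0.5
      al_d <- ifelse(pick, al1[, d], al2[, d])
    }
    al1[, i] <- al_s
    al2[, i] <- al_d
  }
  est <- apply(pairs, 1L, function(p) {
    i <- p[1]; j <- p[2]
    # P(random allele of i == random allele of j), averaged over the 4 picks
    pr <- ((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
           (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])) / 4
    c(a = 2 * mean(pr), se = 2 * stats::sd(pr) / sqrt(n_rep))
  })
  data.frame(i = pairs[, 1], j = pairs[, 2],
             a = est["a", ], se = est["se", ])
}
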