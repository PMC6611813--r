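# Named presets for the spin systems studied with this package, each with a
# sensible default measurement protocol.

#' Names of the built-in fixtures
#' @return Character vector of valid [zulf_fixture()] names.
#' @export
fixture_names <- function() {
  c("AX", "AXB", "formate", "ammonium", "pyruvate", "pyruvate_hydrate")
}

#' Built-in spin-system fixtures
#'
#' \describe{
#'   \item{AX}{1H-13C pair, J = 120 Hz, dissociating as AX <-> A + X (the
#'     exchanged spin is the 13C).}
#'   \item{AXB}{1H(A)-13C(X)-1H(B) with J_AX = 120, J_AB = 3, J_XB = 0 Hz;
#'     the B proton exchanges. Fast B-exchange collapses the multiplet to the
#'     single AX line.}
#'   \item{formate}{same topology with the one-bond J_AX = 222 Hz
#'     (13C-formic acid; B is the acidic proton).}
#'   \item{ammonium}{15NH4+ (A4X), all four N-H couplings 73.4 Hz; proton
#'     exchange by either the single-random-site or the all-sites mechanism
#'     (see [ammonium_pair()]).}
#'   \item{pyruvate}{A3X methyl group of [2-13C]pyruvic acid, J_CH = 6.25 Hz,
#'     exchange-free.}
#'   \item{pyruvate_hydrate}{(A3X)B2: the hydrated form
#'     (2,2-dihydroxypropionic acid) whose two hydroxyl protons (B2, not
#'     J-coupled to the methyl fragment) exchange with water,
#'     (A3X)B2 <-> A3X + 2B. Note the large Liouville dimension; spectrum
#'     simulations of this fixture are expensive.}
#' }
#'
#' @param name One of [fixture_names()].
#' @param mechanism For `"ammonium"` only: `"single"` or `"all"` (see
#'   [ammonium_pair()]).
#' @return A list with elements `name`, `system` (species C), `pair` (an
#'   [exchange_pair()] or NULL for exchange-free fixtures), `protocol`
#'   (default [zulf_protocol()]), and `notes`.
#' @export
#' @examples
#' fx <- zulf_fixture("pyruvate")
#' fx$system
zulf_fixture <- function(name, mechanism = c("single", "all")) {
  name <- match.arg(name, fixture_names())
  mechanism <- match.arg(mechanism)
  switch(name,
    AX = {
      sys <- spin_system(c("1H", "13C"), 120, label = "AX")
      list(name = name, system = sys,
           pair = exchange_pair(sys, traced = 2),
           protocol = zulf_protocol(dwell_s = 1e-3, n_points = 8000),
           notes = "1H-13C pair, J = 120 Hz; dissociation broadens the J line")
    },
    AXB = {
      J <- matrix(c(0, 120, 3,
                    120, 0, 0,
                    3, 0, 0), 3, 3, byrow = TRUE)
      sys <- spin_system(c("1H", "13C", "1H"), J, label = "AXB")
      list(name = name, system = sys,
           pair = exchange_pair(sys, traced = 3),
           protocol = zulf_protocol(dwell_s = 1e-3, n_points = 8000),
           notes = "A,X,B = 1H,13C,1H; J_AX=120, J_AB=3, J_XB=0 Hz; B exchanges")
    },
    formate = {
      J <- matrix(c(0, 222, 3,
                    222, 0, 0,
                    3, 0, 0), 3, 3, byrow = TRUE)
      sys <- spin_system(c("1H", "13C", "1H"), J, label = "formate")
      list(name = name, system = sys,
           pair = exchange_pair(sys, traced = 3),
           protocol = zulf_protocol(dwell_s = 1e-3, n_points = 8000),
           notes = "13C-formic acid: stable 1H-13C fragment at 222 Hz, acidic proton exchanges")
    },
    ammonium = {
      pair <- ammonium_pair(mechanism = mechanism)
      list(name = name, system = pair$system_C, pair = pair,
           protocol = zulf_protocol(dwell_s = 1e-3, n_points = 8000),
           notes = sprintf(
             "15NH4+ A4X, J_NH = 73.4 Hz, '%s' proton-exchange mechanism",
             mechanism))
    },
    pyruvate = {
      n <- 4
      J <- matrix(0, n, n)
      J[1, 2:4] <- 6.25
      J[2:4, 1] <- 6.25
      sys <- spin_system(c("13C", "1H", "1H", "1H"), J,
                         label = "[2-13C]pyruvate")
      list(name = name, system = sys, pair = NULL,
           protocol = zulf_protocol(dwell_s = 1e-3, n_points = 16000),
           notes = "A3X methyl group, J_CH = 6.25 Hz; lines at J and 2J")
    },
    pyruvate_hydrate = {
      n <- 6
      J <- matrix(0, n, n)
      J[1, 2:4] <- 6.25
      J[2:4, 1] <- 6.25
      sys <- spin_system(c("13C", "1H", "1H", "1H", "1H", "1H"), J,
                         label = "pyruvate-hydrate")
      list(name = name, system = sys,
           pair = exchange_pair(sys, traced = c(5, 6)),
           protocol = zulf_protocol(dwell_s = 1e-3, n_points = 16000),
           notes = "(A3X)B2 <-> A3X + 2B hydration exchange; B2 protons uncoupled")
    }
  )
}
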