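# Small hand-checkable scenario used by the economics and CEA unit tests.
# Both arms share exponential survival (shape 1), one priced drug and one
# subsequent therapy; utilities default to 1 so QALYs equal life-years.
toy_scenario <- function(horizon_years = 0.4, discount = 0,
                         u = c(1, 1, 1), drug_price = 100,
                         admin = 10, ct = 0, lab = 0,
                         pfs_scale = 0.2, os_scale = 0.1,
                         ae = list(), sub = list(), ae_costs = list(evt = 10),
                         ...) {
  arm <- function(nm) list(
    name = nm,
    pfs = list(shape = 1, scale = pfs_scale),
    os = list(shape = 1, scale = os_scale),
    treatment = list(type = "components", components = list("drugA")),
    ae = ae,
    subsequent = sub)
  validate_scenario(list(
    population = "toy",
    settings = c(list(horizon_years = horizon_years,
                      annual_discount_rate = discount), list(...)),
    prices = list(drugA = drug_price, subX = 50),
    ae_costs = ae_costs,
    other_costs = list(administration = admin, ct_scan = ct, laboratory = lab),
    utilities = list(pfs_intervention = u[1], pfs_comparator = u[2], pd = u[3]),
    intervention = arm("A"),
    comparator = arm("B"),
    sa_ranges = list()))
}

# parameter ranges chosen so survival stays strictly positive in double
# precision over the cycle indices the tests probe
random_weibull <- function(n, seed) {
  set.seed(seed)
  data.frame(shape = runif(n, 0.3, 2), scale = runif(n, 0.01, 0.3))
}
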