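# crabdeb

Individual-based bioenergetic simulation of non-continuous, biphasic growth
in the pond-cultured swimming crab (*Portunus trituberculatus*), for
aquaculture scientists and modellers who need to predict staged growth,
molt timing and ovarian maturation from a daily temperature series.

## The model

Decapod growth is discontinuous: wet weight jumps at each molt while organic
mass accumulates smoothly in between, and energy allocation shifts sharply
at the puberty molt when ovarian development accelerates. `crabdeb`
implements a dynamic energy budget (DEB) model extended with three
crab-specific mechanisms:

- **α-threshold molting.** The carbon-to-wet-weight ratio α = W_C/W_w (with
  W_C = structure + reserve, ovary excluded) is the internal molting
  indicator. Between molts W_w is fixed by the exoskeleton and α rises; when
  α reaches a stage-specific pre-molt threshold α_pre the crab molts, W_w
  jumps to W_C/α_post (α_post ≈ 0.1) and the cycle restarts. Stage XI is the
  terminal puberty molt.
- **Segmented κ-rule.** Mobilized reserve ṗ_C splits κ to somatic
  maintenance + growth and 1−κ to the reproductive channel, with κ = 1.0 in
  stages I–VII, 0.9 in stages VIII–XI, and 0.2 after the puberty molt.
- **Demand-driven ovary.** Reproductive-buffer energy converts into ovarian
  tissue at a rate ν_G·c(T)·m_ER·(m_Gm − m_G)·W_G, priced at 36,690 J/g
  before and 66,200 J/g after the puberty molt, so ovarian growth is slow
  pre-puberty and rapid after it.

Standard DEB fluxes drive the state: assimilation
ṗ_A = f·ṗ_Am·c(T)·W_G^(2/3), mobilization
ṗ_C = [E]·(E_G·(ṗ_Am/E_m)·c·W_G^(2/3) + ṗ_M·c·W_G)/(E_G + κ[E]), and
maintenance ṗ_S = ṗ_M·c·W_G, all corrected by a single Arrhenius factor
c(T) = exp(T_A/T_ref − T_A/T). Default parameters (T_A = 5482 K,
ṗ_Am = 4590 J g⁻²ᐟ³ d⁻¹, ṗ_M = 310 J g⁻¹ d⁻¹, E_G = 51,180 J g⁻¹,
E_m = 3860 J g⁻¹, μ_E = 18,750 J g⁻¹, β = 0.79, f = 0.9, stage-wise α_pre
from 0.44 down to 0.15) come from oxygen-consumption, starvation, feeding
and molt-ratio experiments; the package also ships the estimators that
produce each of them from such experiment tables, plus synthetic-data
generators to validate every estimator without lab data.

## Worked example

Simulate a 34 g crab over 50 days of a Yellow Sea pond season (16–29 °C
seasonal sinusoid starting May 1); the molt stage is inferred from the
initial weight:

```r
library(crabdeb)
p    <- deb_params()
frc  <- seasonal_forcing(t_min = 16, t_max = 29, horizon = 185)
traj <- deb_simulate(34, p, frc, horizon = 50)
molt_events(traj)
#> # A tibble: 2 × 6
#>     day stage_from stage_to ww_before ww_after alpha_at_trigger
#> 1  21.7          8        9      34       64.6            0.190
#> 2  38.1          9       10      64.6    103.             0.160
glance(traj)
#> # A tibble: 1 × 7
#>   horizon n_molts final_stage ww_total_final wo_final puberty_day starved
#> 1      50       2          10           104.    0.404          NA FALSE
```

The crab molts twice (stage VIII on day 21.7, stage IX on day 38.1), each
molt multiplying the wet weight by α_pre/α_post, and ends the season near
104 g total wet weight — the staged trajectory of a pond cohort that grew
from 34 g to about 100 g over 50 days. Comparing against observed weights
yields the usual fit statistics (`R²`, Nash–Sutcliffe model efficiency,
Theil's U, RMSE):

```r
d <- data.frame(day = c(15, 25, 35, 50), obs = c(41, 60, 72, 95))
d$sim <- traj$ww_total[match(d$day, traj$day)]
goodness_of_fit(d, obs, sim)
#> # A tibble: 1 × 5
#>       n r_squared    me theil_u  rmse
#> 1     4     0.953 0.870  0.0501  7.07
```

`autoplot(traj)` draws the stepped weight curve and the ovary trajectory;
`sensitivity_analysis()` ranks parameters by the ±10% Majkowski index;
`calibrate_gonad()` fits the two ovary coefficients to observed milestones.
A command-line interface wrapping the same functions is installed at
`system.file("cli", "crabdeb.R", package = "crabdeb")`.

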