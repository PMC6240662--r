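# domclpe

Asymmetric item response theory (IRT) calibration for **discrete-option
multiple-choice (DOMC)** test items.

Under the DOMC format an item's response options are shown one at a time in
random order, and the examinee judges each option as correct or incorrect.
The administration stops once the last keyed option has been shown, so the
**scheduled number of response options** `k` — equal to the randomized
position of the last key — varies across administrations of the *same* item,
from `n_keys` up to the item's option count. The item is scored correct only
if every keyed option is endorsed and every administered distractor rejected.
Because each additional scheduled option is one more conjunctive subprocess
to pass, items administered with later key locations are systematically
harder and more discriminating, which raises an equity problem for
examinees who, by chance, drew many late key locations.

`domclpe` addresses this with **Samejima's logistic positive exponent (LPE)
model**. The probability of passing a single option subprocess is a 2PL
logistic,

    Psi_i(theta_j) = exp[a_i (theta_j - b_i)] / (1 + exp[a_i (theta_j - b_i)]),

and the probability of a correct item score raises it to a positive
exponent,

    P(U_i(k),j = 1 | theta_j) = Psi_i(theta_j)^xi_ik,

where the complexity exponent `xi_ik > 0` grows with the scheduled option
count `k`. `xi > 1` produces positively asymmetric item characteristic
curves (conjunctive subprocesses — harder, steeper), `xi < 1` negatively
asymmetric ones, and `xi = 1` recovers the symmetric 2PL. The package
calibrates five competing models of the key-location effect by
Metropolis-within-Gibbs MCMC and compares them by the deviance information
criterion (DIC):

| model  | item parameters                         | k effect |
|--------|-----------------------------------------|----------|
| model1 | 2PL `(a_i, b_i)`                        | none |
| model2 | 2PL `(a_i(k), b_i(k))` per item-by-k cell | on `a` and `b` |
| model3 | 2PL `(a_i, b_i(k))`                     | on `b` only |
| model4 | LPE `(a_i, b_i, xi_ik)`                 | on the exponent |
| model5 | LPE `(a_i, b_i, c_i)` with `xi_ik = c_i k` | linear exponent |

Priors follow the Bayesian LPE literature: `xi ~ Gamma(0.25, 0.25)`,
`b ~ N(0, 1)`, `a ~ Lognormal(0, 0.5)`, `c ~ Gamma(1, 2)`, and
`theta ~ N(0, 1)`, which alone fixes the latent metric under concurrent
calibration of multiple forms linked by shared items.

The package also provides a DOMC administration simulator (random key
location by uniform permutation, conjunctive option-level scoring), a
reference two-form item bank emulating an IT certification test (83 items:
54 single-, 24 double-, 5 triple-keyed; two 59-item forms sharing 35
items), classical item statistics by key location, Gelman-Rubin
diagnostics, and latent-metric shrinkage comparisons between symmetric and
asymmetric calibrations.

Intended users: psychometricians and measurement researchers studying
item-format effects, and testing programs considering IRT-based scoring of
DOMC items.

## Worked example

```r
library(domclpe)

bank <- reference_bank(seed = 1)
sim  <- simulate_responses(bank, sim_config(n_examinees = 300, seed = 2))

# classical difficulty falls and discrimination rises with the number of
# scheduled response options
subset(classical_item_stats(sim$responses)$by_group, n_keys == 1)
#>   n_keys k n_items mean_p mean_item_total_r
#> 1      1 1      54  0.596             0.407
#> 2      1 2      54  0.501             0.408
#> 3      1 3      54  0.390             0.422
#> 4      1 4      54  0.344             0.406

fit <- fit_domc(sim$responses, bank$designs, "model4",
                n_iter = 1000, n_chains = 2, seed = 3)
dic(fit)
#> DIC 16196.0  (D-bar 15600.8, D-hat 15005.6, pD 595.2)

pm <- posterior_summaries(fit)
xi_summary(pm, bank$designs)
#>    n_keys k n_items mean_xi sd_xi
#> 1       1 1      54   0.801 0.656
#> 2       1 2      54   1.106 0.778
#> 3       1 3      54   1.749 1.074
#> 4       1 4      54   2.070 1.236
#> 5       2 2      24   1.192 1.040
#> ...

truth <- bank$true_params; truth$theta <- sim$theta
recovery_report(truth, pm)
#>   block   n    bias  rmse   cor
#> 1 theta 300 -0.0953 0.299 0.964
#> 2     a  83  0.0895 0.344 0.872
#> 3     b  83  0.2387 0.842 0.643
#> 4    xi 303  0.0431 0.940 0.538
```

The classical table shows the key-location effect the models are built for:
mean p-values drop from 0.60 to 0.34 as `k` rises from 1 to 4. The
`xi_summary` table shows the calibrated complexity exponents rising with
`k` within every key-count class, and the recovery report confirms the
generating abilities are recovered (r = 0.96) at this sample size.

A command-line wrapper over the same functions lives at
`inst/scripts/domclpe.R`:

```sh
Rscript inst/scripts/domclpe.R simulate --seed 42 --n-examinees 648 --out sim/
Rscript inst/scripts/domclpe.R fit --responses sim/responses.csv \
    --model 4 --iters 2000 --chains 2 --seed 7 --out fit4/
Rscript inst/scripts/domclpe.R compare --fits fit1,fit4 --out cmp/
```

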