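# selkovsync

Drive–response synchronization of the Selkov glycolysis
reaction–diffusion model, with a linear full-state feedback law and a
Lyapunov-based gain construction.

## The problem

The Selkov system is the minimal two-species kinetic model of glycolytic
oscillations; with diffusion on a domain Ω with zero-flux boundaries it
reads

    ∂t u1 = d1 Δu1 + b u2 − u1 + u1² u2
    ∂t u2 = d2 Δu2 + a − b u2 − u1² u2,     ∂ν u1 = ∂ν u2 = 0 on ∂Ω,

with positive constants a, b, d1, d2.  Given an autonomous *drive* copy
of this system, the package forces a controlled *response* copy
(states v1, v2, controls U1, U2) onto the drive trajectory.  With the
error e = (v1 − u1, v2 − u2), the control law

    U1 = −(2K − 1) e1 − b e2,     U2 = −(2K − b) e2

turns the error dynamics into ∂t e_i = d_i Δe_i − 2K e_i ± (v1²v2 − u1²u2),
and the Lyapunov functional V = ½∫(e1² + e2²) decreases monotonically
whenever K ≥ max{K3², K2(K1 + K3)}, where K1, K2, K3 are sup-norm bounds
on u1, u2, v1.  The package implements the kinetics and their linear
(Turing) stability analysis, an explicit finite-difference solver with
Neumann boundaries in 1D and 2D, the control law and its gain pipeline,
and synchronization diagnostics (L2 error, Lyapunov series, boundedness
and positivity monitors).  It is aimed at researchers studying
synchronization and pattern formation in reaction–diffusion systems.

## Worked example

The reference experiment: Ω = [0,10] at spacing 0.2 (51 nodes),
(d1, d2, a, b) = (0.01, 1, 3.5, 0.25), sinusoidal drive and response
initial conditions, gain K = 15, horizon t ∈ [0, 100].

```r
library(selkovsync)

p <- selkov_params()            # a = 3.5, b = 0.25, d1 = 0.01, d2 = 1
g <- rd_grid(1, 10, 51)         # [0, 10], spacing 0.2

turing_analysis(p)
#> Turing stability analysis of the Selkov steady state
#>   steady state      : (3.5, 0.28)
#>   trace, determinant: -11.54, 12.5
#>   homogeneous stable: TRUE
#>   Turing unstable   : TRUE
#>   max growth rate   : 0.0956714 at k^2 = 35.6293  (65 modes sampled)

sync <- synchronize(ic_drive_reference(g), ic_response_reference(g), p,
                    control_gains(15, p), time_config(t_end = 100))
sync
#> Drive-response synchronization run: K = 15, t in [0, 100], dt = 0.01125
#>   L2 error: 7.1965 -> 0 (ratio 0)

head(sync$diagnostics[, c("time", "l2_error", "lyapunov_v")], 4)
#>   time l2_error lyapunov_v
#> 1    0 7.196496   25.89478
#> 2    4 0.000000    0.00000
#> 3    8 0.000000    0.00000
#> 4   12 0.000000    0.00000
```

The kinetics at these parameters are stable (negative trace, positive
determinant) but diffusion destabilizes a band of spatial modes — the
drive develops a stationary Turing pattern — yet the controlled response
locks onto it: the L2 error falls from 7.2 to numerical zero within the
first snapshot interval, and V(t) is non-increasing throughout.  With the
feedback zeroed the error ratio stays near 0.12 over the same horizon.

Gains can also be constructed rather than supplied: `auto_gains()` runs
the uncontrolled systems, bounds the fields (safety margin 1.2), and
applies the `lemma2_gain()` formula.

A thin command-line interface is installed at `inst/cli/selkovsync`:

```sh
Rscript inst/cli/selkovsync make-config --out run.yaml
Rscript inst/cli/selkovsync synchronize --config run.yaml --out-dir out/
Rscript inst/cli/selkovsync stability --config run.yaml
```

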