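# Example hessgaze run configuration (all values shown are the defaults).
# Any key may be omitted; unknown keys are rejected.

[geometry]
screen_distance_cm = 100   # subject to Hess grid
square_cm = 5              # one grid square = 5 prism diopters at 1 m
tracker_distance_cm = 60
tracker_max_angle_deg = 35

[dwell]
radius_cm = 7.5            # 1.5 squares around each target
min_duration_s = 0.3
min_valid_frac = 0.8
dispersion_max_cm = 6.0    # I-DT threshold; see the methods vignette
selection = "last"         # the subject's final confirmed placement
max_missing_frac = 0.5
center = "median"

[deviation]
central_only = true        # analyze the nine central targets only
tol_pd = 0.5
min_valid_floor = 10

[stats]
alpha = 0.05
ks_mode = "lilliefors"

[simulator]
n_subjects = 1
phoria_h_pd = 0.0          # esophoria +, exophoria -
phoria_v_pd = 0.0          # RE hyperphoria +
noise_deg_rms = 0.3
dwell_s = 2.0
saccade_ms = 40
blink_rate_hz = 0.2
blink_ms = 150
loss_prob = 0.005
rate_hz = 250
seed = 1
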