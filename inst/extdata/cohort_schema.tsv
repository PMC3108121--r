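column	type	units	description
subject_id	character	-	unique subject label (W/P/E prefix for simulated cohorts)
group	character	-	one of WELDER, IPD, ET
age	numeric	years	age at recording
sex	character	-	M or F
age_at_onset	numeric	years	age at symptom onset (NA if unknown)
years_exposure	numeric	years	welding-fume exposure duration (welders only, else NA)
years_since_exposure	numeric	years	time since last exposure (welders only, else NA)
initial_tremor	integer	0/1	tremor reported as an initial symptom
initial_bradykinesia	integer	0/1	slowness reported as an initial symptom
initial_balance	integer	0/1	balance difficulty reported as an initial symptom
initial_limb_cramping	integer	0/1	limb cramping reported as an initial symptom
resting_tremor	integer	0/1	resting tremor on examination
action_tremor	integer	0/1	action tremor on examination
postural_tremor	integer	0/1	postural tremor on examination
dystonic_limb	integer	0/1	dystonic limb posture on examination
cogwheel_rigidity	integer	0/1	cog-wheel rigidity on examination
asymmetric_tremor	integer	0/1	right/left asymmetric tremor
asymmetric_rigidity	integer	0/1	right/left asymmetric rigidity
asymmetric_bradykinesia	integer	0/1	right/left asymmetric bradykinesia
dyshidrosis	integer	0/1	excessive sweating by history
dizziness_standing	integer	0/1	orthostatic dizziness by history
<condition>_<side>_<metric>	numeric	varies	attached tremor metrics, e.g. rest_R_intensity (m/s^2), postural_L_center_freq (Hz); metrics: intensity, center_freq, median_freq, dispersion, low_band_fraction, high_band_fraction, harmonic_index
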