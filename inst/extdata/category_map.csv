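category,code
asthma,J45
hypertension,I10
respiratory_failure,J96.0
respiratory_failure,J96.1
respiratory_failure,J96.9
smoking,Z72.0
smoking,J43.9
smoking,F17.2
candidiasis,B37.0
candidiasis,B37.1
candidiasis,B37.7
candidiasis,J31.0
obesity,E11.9
obesity,E11.8
obesity,E66.0
obesity,E66.9
obesity,G47.32
obesity,G47.30
obesity,R73
obesity,E78.5
obesity,E78.0
obesity,E78.2
hepatic,K76.0
hepatic,R74.0
hepatic,B18.1
hepatic,B18.2
respiratory_infections,J15.0
respiratory_infections,J15.1
respiratory_infections,J15.2
respiratory_infections,J15.6
respiratory_infections,J15.8
respiratory_infections,J15.9
respiratory_infections,J18.0
respiratory_infections,J18.8
respiratory_infections,J18.9
respiratory_infections,J12.9
respiratory_infections,J47
respiratory_infections,B90.9
respiratory_infections,A15.0
respiratory_infections,Z11.5
lung_fibrosis,J84.1
lung_fibrosis,J84.9
allergies,J30.4
allergies,J30.1
urinary,N39.0
urinary,N40
urinary,N18.90
urinary,N20.9
urinary,N02.9
urinary,R31
sepsis_and_death,A41.9
sepsis_and_death,A41.8
sepsis_and_death,E87.0
sepsis_and_death,E87.1
sepsis_and_death,E87.2
sepsis_and_death,E87.5
sepsis_and_death,E87.6
sepsis_and_death,E87.8
sepsis_and_death,E86
sepsis_and_death,I46.9
anemia,D53.9
anemia,D64.8
anemia,D64.9
anemia,D63.8
anemia,D50.8
covid19,U07.1
copd,J44
copd,J44.0
copd,J44.1
copd,J44.8
copd,J44.9
copd,J42
copd,J41.0
copd,J43.8
copd,Z99.1
copd,J94.8
pleural,J90
pleural,J92.0
pleural,J92.9
cardiovascular,I25.9
cardiovascular,I50.0
cardiovascular,I27.9
cardiovascular,I34.0
cardiovascular,E79.0
cardiovascular,I11.0
cardiovascular,I27.0
cardiovascular,I50.9
cardiovascular,I47.1
cardiovascular,I48
cardiovascular,I36.1
cardiovascular,I20.9
cardiovascular,I45.0
cardiovascular,I07.1
cardiovascular,I70.0
cardiovascular,I20.8
cardiovascular,I25.2
cardiovascular,I49.3
cardiovascular,I30.9
cardiovascular,I27.2
cardiovascular,I26.9
cardiovascular,I70.8
cardiovascular,I35.1
cardiovascular,I35.0
cardiovascular,I25.5
cardiovascular,I25.8
cardiovascular,I11.9
cardiovascular,I27.8
cardiovascular,R00.0
cardiovascular,I44.0
cardiovascular,I44.7
cardiovascular,I50.1
cardiovascular,I45.1
cardiovascular,I25.0
cardiovascular,I49.8
cardiovascular,I70.9
cardiovascular,I42.0
cardiovascular,I25.6
cardiovascular,I49.1
cardiovascular,I35.2
cardiovascular,I20.0
cardiovascular,I49.4
neurological,G20
neurological,G31.0
neurological,I63.8
neurological,I63.9
neurological,I24.9
neurological,R42
neurological,I69.3
neurological,F03
neurological,F06.7
psychiatric,F41.2
psychiatric,F41.9
psychiatric,F06.6
psychiatric,F33.9
gerd,K21.0
gerd,K21.9
cancer,C34.0
cancer,C34.1
cancer,C34.8
cancer,C34.9
cancer,C78.0
cancer,R59.0
cataracts,H26.9
addiction,F10.2
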