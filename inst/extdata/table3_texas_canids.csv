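# Sample information for 10 Texas canids from the 1970s red wolf founder
# capture efforts, transcribed from the published table. Red wolf ancestry
# proportions are from previously published whole-genome analyses. The
# starred column reproduces the asterisk annotation on sample ids.
sample,county,rw_ancestry,collection_date,starred
70-TX-01,Webb,0.02,1976-03-22,FALSE
70-TX-02,Webb,0.02,1976-03-23,FALSE
70-TX-03,Jefferson,0.11,1976-01-24,TRUE
70-TX-04,Jefferson,0.52,1976-01-25,TRUE
70-TX-05,Harris,0.19,1976-01-04,TRUE
70-TX-06,Montague,0.02,1975-11-21,FALSE
70-TX-07,Brazoria,0.03,1975-02-02,TRUE
70-TX-08,Liberty,0.27,1975-07-31,TRUE
70-TX-09,Brazoria,0.29,1975-05-07,TRUE
70-TX-10,Webb,0.02,1976-03-23,FALSE
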