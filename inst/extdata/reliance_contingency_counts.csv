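metric,advice_correct,condition,n_not,n_yes
acceptance,incorrect,distrust,1490,1182
acceptance,incorrect,information-only,1657,1413
acceptance,correct,distrust,1562,8942
acceptance,correct,information-only,1704,10346
switch,incorrect,distrust,1181,616
switch,incorrect,information-only,1329,709
switch,correct,distrust,891,2583
switch,correct,information-only,1067,3044
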