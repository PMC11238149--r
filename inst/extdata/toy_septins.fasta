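>toy_s1 synthetic toy septin fixture
DQPSTPTNSAAGPDAADDAATDRRKKKRRKRRRKDPEGPNGETTGGSNNEGPGEPSQEDDWKHFCMFGQSGLGKSAVWED
PVNAKMEEIVQLGCSGYRRAMGDMWCAARTWKYPLNESYFCAIWHYMIMYSLNIKQHLSCCNTEEEIATMGWVRQLWEFR
RTMCWMHENIQYYSQASLITNQCHNFLTRNEPTTCNPFMNWYRYCPSVDKLIHHHSKWTQCACVRMVYQMKEWYHVCIVW
ETINREMERCAEIKVSEEYEPMVNEEQIKIASGRWRQYWPHWDYASKAKTKLDHDRNSRHKCLALMIHLGAHAHLTGFRW
WINPTSHSKWAEHRSQVGQGPFCGVYLINLNQEMYWFMHCAGSDPPNGTPNTSEAPEAGESLTKVYRSYFDYYQQILEAE
>toy_s2 synthetic toy septin fixture
AGGERKRKKRKRKRKRSGDQGDEGNDPEGTPTNQNSPDSTEQATAGPTGQQDTGGNNEGSWKHFCMFGQSGLGKSAVWED
PVNAKMEEIVQLGCSGYRRAMGDMWCAARTWKYPLNESYFCAIWHYMIMYSLNIKQHLSCCNTEEEIATMGWVRQLWEFR
RTMCWMHENIQYYSQASLITNQCHNFLTRNEPTTCNPFMNWYRYCPSVDKLIHHHSKWTQCACVRMVYQMKEWYHVCIVW
ETINREMERCAEIKVSEEYEPMVNEEQIKIASGRWRQYWPHWDYASKAKTKLDHDRNSRHKCLALMIHLGAHAHLTGFRW
WINPTSHSKWAEHRSQVGQGPFCGVYLINLNQEMYWFMHCADAITKMVEQYWRLWTSIYDQDANSPDANNGSTQDSPNAE
>toy_s3 synthetic toy septin fixture
APQEEQRRRKKKRRKKKRGTDEGNGEPNAPGEQSNGQDPSDSDATGEQDNQTSQGSTATEWKHFCMFGQSGLGKSAVWED
PVNAKMEEIVQLGCSGYRRAMGDMWCAARTWKYPLNESYFCAIWHYMIMYSLNIKQHLSCCNTEEEIATMGWVRQLWEFR
RTMCWMHENIQYYSQASLITNQCHNFLTRNEPTTCNPFMNWYRYCPSVDKLIHHHSKWTQCACVRMVYQMKEWYHVCIVW
ETINREMERCAEIKVSEEYEPMVNEEQIKIASGRWRQYWPHWDYASKAKTKLDHDRNSRHKCLALMIHLGAHAHLTGFRW
WINPTSHSKWAEHRSQVGQGPFCGVYLINLNQEMYWFMHCQDAGPPNEQAEPDTDADPSEEDTTPNSGGESDAPTANQNN
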