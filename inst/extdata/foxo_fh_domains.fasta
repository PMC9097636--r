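>FOXO1 Q12778 159 245 human FOXO1 forkhead domain (bundled reference copy)
AWGNLSYADLITKAIESSAEKRLTLSQIYEWMVKSVPYFKDKGDSNSSAGWKNSIRHNLS
LHSKFIRVQNEGTGKSSWWMLNPEGGK
>FOXO3 O43524 156 242 human FOXO3 forkhead domain (bundled reference copy)
AWGNLSYADLITKAIESSPDKRLTLSQIYEWMVRCVPYFKDKGDSNSSAGWKNSIRHNLS
LHSKFIRVQNEGTGKSSWWMINPDGGK
>FOXO4 P98177 100 186 human FOXO4 forkhead domain (bundled reference copy)
AWGNQSYAELISQAIESAPEKRLTLAQIYEWMVRTVPYFKDKGDSNSSAGWKNSIRHNLS
LHSKFIRVQNEGTGKSSWWMLNPEGGK
>FOXO6 A8MYZ6 87 173 human FOXO6 forkhead domain (bundled reference copy)
AWGNLSYADLITRAIESSPDKRLTLSQIYEWMVRYVPYFKDKGDSNSSAGWKNSIRHNLS
LHSKFIRVQNEGTGKSSWWMLNPEGGK
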