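>CthedisKatG_syn synthetic stand-in, 723 aa natural chain + 6xHis tag
QHFQINGIFVIFQAKVSADVGNLDDGELFRQEVSGSIEDLFDNAKISDQQLDGAQEGEQR
ITSLLILNEVFNIFKDTLVAITEEITNNNWVGFVSGVESHQELGRVINTQNVNETLVHTK
LINAADHENGVVTERQGAIDNIHFVSDLLKVATFILTQHALHAGRHTQFQILSTIQQDAK
ADTHLLEQQTSEQGRVSLTTFTSNLATHNKISNNSTDYHDTDHNRNGDTESNEAAELESK
ETHMGGIAQNQNNQRHNEEESDSDAEDAQKDGDTVSHDFGQNAIRSFQTAGNIVVNEGGK
IAFQVQISEGDDNTRQNDALIADAGQAASKFADEFAEHVNSATVRSDDLFTHVSTDHSAK
AFHDIIISVDFGSTRHIENEQVFLNFHFAKEDFFSEINHQFSHDRQDGIHGSAEVAEIIK
SIQVVGVQLSGDFARLGEHVDFVTTFFINKSDVFDQVLVFTGESRDTQFSVNVFDIVSDK
FNGVQISEIDAHGHRHENGGGISVGNNEEKHHGESDVNIFTLILRDIATEQNDEQAHTAK
ASQNTFTALLTEIDRSHFILFQDSDVVHAKFFVEDQEQGSFNLTRNGGLNLSFTLATIGK
LFLNNSQTNDIFHHRVHSQADEASVLQVAKTDSEHGFFFQAIAQRDFGLLNGTSNLFINK
LGISSNQNTIDVGTREFAIGFHFEDTGFEKIASTNLNIVENNQAREISIQDAVHIVSHGH
IETHHHHHH
>MagKatG1_syn synthetic stand-in, 750 aa natural chain + 6xHis tag
QHFQINGIFVIFQAKVSADVGNLDDGELFRQEVSGSIEDLFDNAKISDQQLDGAQEGEQR
ITSLLILNEVFNIFKDTLVAITEEITNNNWVGFVSGVESHQELGRVINTQNVNETLVHTK
LINAADHENGVVTERQGAIDNIHFVSDLLKVATFILTQHALHAGRHTQFQILSTIQQDAK
ADTHLLEQQTSEQGRVSLTTFTSNLATHNKISNNSTDNHDTDHNRNGDTESNEAAELYSK
ETHNGGIAQNQNNQRHNEEESDSMAEDAQKDGDTVSHDFGQNAIRSFQTAGNIVVNEGGK
IAFQVQISEGDDNTRQNDALIADAGQAASKFADEFAEHVNSATVRSDDLFTHVSTDHSAK
AFHDIIISVDFGSTRHIENEQVFLNFHFAKEDFFSEINHQFSHDRQDGIHGSAEVAEIIK
SIQVVGVQLSGDFARLGEHVDFVTTFFINKSDVFDQVLVFTGESRDTQFSVNVFDIVSDK
FNGVQISEIDAHGHRHENGGGISVGNNEEKHHGESDVNIFTLILRDIATEQNDEQAHTAK
ASQNTFTALLTEIDRSHFILFQDSDVVHAKFFVEDQEQGSFNLTRNGGLNLSFTLATIGK
LFLNNSQTNDIFHHRVHSQADEASVLQVAKTDSEHGFFFQAIAQRDFGLLNGTSNLFINK
LGISSNQNTIDVGTREFAIGFHFEDTGFEKIASTNLNIVENNQAREISIQDAVHIVSHGK
IETNNEAIFTEGNQRDVAFVVDVSNVDNDVHHHHHH
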